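# GWAS <-> eQTL integration: exact rsID matching of GWAS variants against
# per-tissue lead cis-eQTL tables and consolidation into per-disease
# datasets.

#' Build an rsID match index over a per-tissue egenes panel
#'
#' Collapses a panel of per-tissue egenes tables into a single index keyed
#' by normalized rsID. The GTEx sentinel `"."` (no dbSNP identifier) is
#' excluded from the index: such lead eQTLs exist but can never be matched
#' by rsID. Matching downstream is exact and literal -- no positional or
#' fuzzy matching.
#'
#' @param egenes_panel either a named list of egenes tibbles (one per
#'   tissue, as from [read_egenes()]) or a single combined tibble with a
#'   `tissue` column.
#' @return an object of class `eqtl_index` wrapping the indexed rows;
#'   `length()` gives the number of distinct indexed rsIDs.
#' @seealso [match_variants()]
#' @export
build_match_index <- function(egenes_panel) {
  if (is.data.frame(egenes_panel)) {
    combined <- egenes_panel
  } else {
    combined <- bind_rows(egenes_panel)
  }
  if (nrow(combined) > 0) {
    combined <- combined %>%
      mutate(rs_id = normalize_rsid(rs_id)) %>%
      filter(rs_id != ".")
  }
  structure(list(table = combined), class = "eqtl_index")
}

#' @export
length.eqtl_index <- function(x) length(unique(x$table$rs_id))

#' @export
print.eqtl_index <- function(x, ...) {
  cat("eQTL match index:", length(x), "distinct rsIDs,",
      nrow(x$table), "variant-gene-tissue rows\n")
  invisible(x)
}

#' Match GWAS variants against the eQTL index by exact rsID
#'
#' Aligns GWAS rsIDs with the GTEx identifier column; only exact rsID
#' matches are retained. Each hit yields one record per (variant, gene,
#' tissue) carrying the regulated gene, the nominal p-value, the
#' multiple-testing-corrected q-value, the effect size (slope, expression
#' change per copy of the alternate allele) and the variant's disease
#' group. Records are kept when `qval <= qval_threshold` (the GTEx eGene
#' significance convention, q <= 0.05, by default).
#'
#' @param gwas_variants GWAS variant tibble with normalized rsIDs.
#' @param index an `eqtl_index` from [build_match_index()].
#' @param qval_threshold maximum q-value for a record to be retained.
#' @return tibble of eQTL records sorted by (tissue, gene_name, rsid):
#'   columns `rsid`, `gene_name`, `tissue`, `slope`, `pval_nominal`,
#'   `qval`, `group`.
#' @export
match_variants <- function(gwas_variants, index, qval_threshold = 0.05) {
  stopifnot(inherits(index, "eqtl_index"))
  empty <- tibble(rsid = character(), gene_name = character(),
                  tissue = character(), slope = double(),
                  pval_nominal = double(), qval = double(),
                  group = character())
  if (nrow(gwas_variants) == 0 || nrow(index$table) == 0) return(empty)

  hits <- dplyr::inner_join(
    tibble(rsid = normalize_rsid(gwas_variants$rsid),
           group = gwas_variants$group),
    index$table,
    by = c("rsid" = "rs_id"),
    relationship = "many-to-many"
  )
  hits %>%
    filter(qval <= qval_threshold) %>%
    dplyr::select(rsid, gene_name, tissue, slope, pval_nominal, qval, group) %>%
    arrange(tissue, gene_name, rsid)
}

#' Consolidate eQTL records into per-gene regulatory datasets
#'
#' Partitions matched records into genes regulated in a single tissue and
#' genes regulated in two or more distinct tissues (the multi-tissue set on
#' which directional-consistency analysis operates), and assembles each
#' gene's tissue-to-slope profile. Genes are consolidated within their
#' disease group: the same symbol appearing in both groups is treated as
#' two profiles.
#'
#' @param records eQTL record tibble from [match_variants()].
#' @return a list: `profiles` (tibble with `group`, `gene_name`,
#'   `n_tissues` and list columns `tissues`, `slopes`),
#'   `single_tissue_genes` and `multi_tissue_genes` (character vectors of
#'   gene symbols), and the input `records`.
#' @export
consolidate_records <- function(records) {
  if (nrow(records) == 0) {
    return(list(
      profiles = tibble(group = character(), gene_name = character(),
                        n_tissues = integer(), tissues = list(),
                        slopes = list()),
      single_tissue_genes = character(),
      multi_tissue_genes = character(),
      records = records
    ))
  }
  profiles <- records %>%
    arrange(group, gene_name, tissue) %>%
    group_by(group, gene_name) %>%
    summarise(
      n_tissues = dplyr::n_distinct(tissue),
      tissues = list(tissue),
      slopes = list(slope),
      .groups = "drop"
    )
  list(
    profiles = profiles,
    single_tissue_genes = sort(profiles$gene_name[profiles$n_tissues == 1]),
    multi_tissue_genes = sort(profiles$gene_name[profiles$n_tissues >= 2]),
    records = records
  )
}
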