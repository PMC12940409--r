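# Variant cataloguing: significance filtering, chromosomal distribution,
# group overlap, consequence tabulation, gene recurrence and top-variant
# ranking.

# duplicate rsIDs within one group are counted once, keeping the smallest p
dedupe_variants <- function(variants) {
  if (anyDuplicated(variants$rsid)) {
    warning("duplicate rsID(s) within group deduplicated (smallest p kept): ",
            paste(unique(variants$rsid[duplicated(variants$rsid)]),
                  collapse = ", "),
            call. = FALSE)
    variants <- variants %>%
      arrange(p_value, rsid) %>%
      distinct(rsid, .keep_all = TRUE)
  }
  variants
}

#' Filter variants at an association significance threshold
#'
#' Retains exactly the variants with `p_value` strictly below `threshold`
#' (the relaxed GWAS threshold used throughout the pipeline is
#' p < 1e-5), preserving input order. The inequality is strict: a variant
#' with p exactly at the threshold is dropped.
#'
#' @param variants GWAS variant tibble ([read_gwas_table()]).
#' @param threshold significance threshold in (0, 1).
#' @return the filtered tibble.
#' @export
filter_by_significance <- function(variants, threshold = 1e-5) {
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            threshold > 0, threshold < 1)
  variants[variants$p_value < threshold, , drop = FALSE]
}

#' Chromosomal distribution of variants
#'
#' Counts variants per chromosome over the full label set 1-22, X, Y;
#' chromosomes without variants are reported with a zero count so the
#' distribution always has 24 rows. Duplicate rsIDs within the input are
#' counted once.
#'
#' @param variants GWAS variant tibble.
#' @return tibble with columns `chromosome` (ordered 1-22, X, Y) and `n`;
#'   counts sum to the deduplicated input size.
#' @export
chromosome_distribution <- function(variants) {
  variants <- dedupe_variants(variants)
  counts <- table(factor(variants$chromosome, levels = .chromosome_levels))
  tibble(chromosome = .chromosome_levels, n = as.integer(counts))
}

#' Overlap between two variant groups
#'
#' Partitions two groups of variants (membership by normalized rsID) into
#' exclusive-to-A, exclusive-to-B and shared sets. Duplicate rsIDs within
#' a group are deduplicated with a warning before comparison.
#'
#' @param variants_a,variants_b GWAS variant tibbles.
#' @return an object of class `overlap_summary`: a list with sorted rsID
#'   vectors `exclusive_a`, `exclusive_b`, `shared` and counts
#'   `n_exclusive_a`, `n_exclusive_b`, `n_shared`, `n_a`, `n_b`.
#' @examples
#' a <- tibble::tibble(rsid = c("rs1", "rs2"), p_value = c(1e-8, 1e-9))
#' b <- tibble::tibble(rsid = c("rs2", "rs3"), p_value = c(1e-7, 1e-6))
#' overlap_summary(a, b)$n_shared # 1
#' @export
overlap_summary <- function(variants_a, variants_b) {
  a <- unique(dedupe_variants(variants_a)$rsid)
  b <- unique(dedupe_variants(variants_b)$rsid)
  out <- list(
    exclusive_a = sort(setdiff(a, b)),
    exclusive_b = sort(setdiff(b, a)),
    shared = sort(intersect(a, b))
  )
  out$n_exclusive_a <- length(out$exclusive_a)
  out$n_exclusive_b <- length(out$exclusive_b)
  out$n_shared <- length(out$shared)
  out$n_a <- length(a)
  out$n_b <- length(b)
  structure(out, class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("Variant group overlap\n")
  cat("  group A:", x$n_a, "variants (", x$n_exclusive_a, "exclusive )\n")
  cat("  group B:", x$n_b, "variants (", x$n_exclusive_b, "exclusive )\n")
  cat("  shared :", x$n_shared, "\n")
  invisible(x)
}

#' Tabulate variants by most-severe consequence class
#'
#' Counts deduplicated variants per consequence class; all nine classes are
#' always present (zeros included), in canonical order. An unrecognised
#' class string is fatal.
#'
#' @param variants GWAS variant tibble.
#' @return tibble with columns `consequence` and `n`; `sum(n)` equals the
#'   deduplicated input size.
#' @export
consequence_table <- function(variants) {
  variants <- dedupe_variants(variants)
  token <- normalize_consequence(variants$consequence)
  counts <- table(factor(token, levels = .consequence_levels))
  tibble(consequence = .consequence_levels, n = as.integer(counts))
}

#' Gene recurrence across variant annotations
#'
#' Counts how often each mapped-gene annotation recurs across variants.
#' Multi-gene annotations (intergenic variants flanked by two genes) are
#' canonicalized order-insensitively -- the pairs (ADAMTS2, U4) and
#' (U4, ADAMTS2) collapse onto one label -- so recurrence reflects the
#' gene combination, not its printed order.
#'
#' @param variants GWAS variant tibble.
#' @return tibble with columns `gene_label` (sorted symbols joined by
#'   `", "`) and `n`, sorted by decreasing count then label.
#' @export
gene_recurrence <- function(variants) {
  variants <- dedupe_variants(variants)
  labels <- vapply(variants$mapped_genes,
                   function(g) paste(sort(g), collapse = ", "), "")
  labels <- labels[nzchar(labels)]
  counts <- sort(table(labels), decreasing = TRUE)
  out <- tibble(gene_label = names(counts), n = as.integer(counts))
  out[order(-out$n, out$gene_label), ]
}

#' Top-ranked variants by association significance
#'
#' Ranks variants by ascending p-value (ties broken by lexicographic
#' rsID). With `per_chromosome = TRUE` the top `n` variants of every
#' chromosome are reported, mirroring per-chromosome summary tables.
#'
#' @param variants GWAS variant tibble.
#' @param n number of variants to report (per chromosome if
#'   `per_chromosome`); if `n` exceeds the available variants the whole
#'   sorted list is returned.
#' @param per_chromosome report the top `n` within each chromosome.
#' @return the ranked variant tibble.
#' @export
top_variants <- function(variants, n = 10, per_chromosome = FALSE) {
  stopifnot(n >= 1)
  variants <- dedupe_variants(variants) %>% arrange(p_value, rsid)
  if (!per_chromosome) {
    return(head(variants, n))
  }
  variants %>%
    group_by(chromosome) %>%
    dplyr::slice_head(n = n) %>%
    ungroup() %>%
    arrange(factor(chromosome, levels = .chromosome_levels), p_value, rsid)
}
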