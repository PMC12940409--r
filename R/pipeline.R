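# End-to-end orchestration: read a data directory, run every analysis
# stage, and write the result tables plus a JSON run manifest.

#' Pipeline run configuration
#'
#' Collects input paths, thresholds and options for [run_pipeline()].
#' Tissue labels for egenes files are inferred from the filename stem
#' (everything before the first `.`), matching the one-file-per-tissue
#' layout of GTEx egenes releases; `tissue_overrides` remaps stems that
#' do not follow it.
#'
#' @param gwas_eoad,gwas_load paths to the two GWAS association TSVs.
#' @param egenes_dir directory of per-tissue egenes files.
#' @param out_dir output directory for result tables and the manifest.
#' @param tpm optional named character vector of TPM matrix paths; each
#'   yields a clustering output named after it.
#' @param edges optional named character vector of edge-list paths; each
#'   yields a network summary.
#' @param annotation optional term-to-gene TSV (columns `term`, `gene`)
#'   used, with `background_n`, to enrich each network's node set.
#' @param background_n background gene count for enrichment.
#' @param significance_threshold GWAS significance cut-off (strict `<`).
#' @param qval_threshold eGene q-value cut-off for matches.
#' @param min_confidence interaction confidence cut-off for edge lists.
#' @param tissues tissue panel; egenes files whose tissue is outside the
#'   panel are reported by [validate_run_inputs()] and skipped.
#' @param tissue_overrides named character vector, filename stem ->
#'   tissue label.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(gwas_eoad, gwas_load, egenes_dir, out_dir,
                            tpm = NULL, edges = NULL, annotation = NULL,
                            background_n = NULL,
                            significance_threshold = 1e-5,
                            qval_threshold = 0.05,
                            min_confidence = 0.4,
                            tissues = tissue_panel(),
                            tissue_overrides = NULL) {
  stopifnot(significance_threshold > 0, significance_threshold < 1,
            qval_threshold > 0, qval_threshold < 1)
  structure(list(
    gwas_eoad = gwas_eoad, gwas_load = gwas_load,
    egenes_dir = egenes_dir, out_dir = out_dir,
    tpm = tpm, edges = edges, annotation = annotation,
    background_n = background_n,
    significance_threshold = significance_threshold,
    qval_threshold = qval_threshold,
    min_confidence = min_confidence,
    tissues = tissues, tissue_overrides = tissue_overrides
  ), class = "run_config")
}

egenes_files <- function(config) {
  files <- sort(list.files(config$egenes_dir, full.names = TRUE))
  files <- files[!dir.exists(files)]
  stems <- sub("\\..*$", "", basename(files))
  if (!is.null(config$tissue_overrides)) {
    hit <- stems %in% names(config$tissue_overrides)
    stems[hit] <- config$tissue_overrides[stems[hit]]
  }
  setNames(files, stems)
}

#' Validate pipeline inputs without running the pipeline
#'
#' Report-only schema and panel check of every configured input file:
#' missing files and missing required columns are reported at level
#' `"fatal"` (they would abort [run_pipeline()]); egenes files whose
#' inferred tissue is outside the configured panel are level
#' `"warning"` (they would be skipped). Inputs are never modified.
#'
#' @param config a [pipeline_config()].
#' @return tibble with columns `file`, `level`, `message`; zero rows for
#'   a clean configuration.
#' @export
validate_run_inputs <- function(config) {
  issues <- list()
  note <- function(file, level, message) {
    issues[[length(issues) + 1]] <<- tibble(file = file, level = level,
                                            message = message)
  }
  check_cols <- function(path, required) {
    if (!file.exists(path)) {
      note(path, "fatal", "file not found")
      return()
    }
    hdr <- names(read_tsv_raw(path))
    missing <- setdiff(required, hdr)
    if (length(missing) > 0) {
      note(path, "fatal",
           paste("missing required column(s):",
                 paste(missing, collapse = ", ")))
    }
  }
  check_cols(config$gwas_eoad, c("rsid", "chromosome", "position",
                                 "p_value", "mapped_genes", "consequence"))
  check_cols(config$gwas_load, c("rsid", "chromosome", "position",
                                 "p_value", "mapped_genes", "consequence"))
  if (!dir.exists(config$egenes_dir)) {
    note(config$egenes_dir, "fatal", "egenes directory not found")
  } else {
    files <- egenes_files(config)
    for (i in seq_along(files)) {
      check_cols(files[i], c("gene_id", "gene_name",
                             "rs_id_dbSNP151_GRCh38p7", "pval_nominal",
                             "slope", "qval"))
      if (!(names(files)[i] %in% config$tissues)) {
        note(files[i], "warning",
             paste0("tissue '", names(files)[i],
                    "' not in the configured panel; file will be skipped"))
      }
    }
  }
  for (p in c(config$tpm, config$edges, config$annotation)) {
    if (!file.exists(p)) note(p, "fatal", "file not found")
  }
  if (length(issues) == 0) {
    return(tibble(file = character(), level = character(),
                  message = character()))
  }
  bind_rows(issues)
}

#' Run the full analysis pipeline
#'
#' Executes every stage over a data directory: reads and
#' significance-filters both GWAS tables; writes top-variant,
#' chromosome-distribution, overlap, consequence and gene-recurrence
#' tables; matches variants against the egenes panel by exact rsID;
#' writes the variant-gene-tissue record table and per-gene slope
#' profiles; hierarchically clusters any configured TPM matrices; and
#' summarises any configured interaction networks (with term enrichment
#' when an annotation table is configured). A JSON manifest echoes the
#' configuration, input checksums and the record counts at every stage.
#'
#' Identical inputs and configuration produce byte-identical outputs.
#' Any stage failure aborts with the stage name; files already written
#' for the failed run are removed.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (list); side effect: result tables
#'   and `manifest.json` under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write_tsv_plain(as.data.frame(df), path)
    written <<- c(written, path)
    path
  }
  stage <- "setup"
  manifest <- list(config = list(
    significance_threshold = config$significance_threshold,
    qval_threshold = config$qval_threshold,
    min_confidence = config$min_confidence,
    tissues = config$tissues
  ))

  result <- tryCatch({
    stage <- "read_gwas"
    eoad <- read_gwas_table(config$gwas_eoad, "EOAD")
    load_ <- read_gwas_table(config$gwas_load, "LOAD")

    stage <- "catalog"
    eoad <- filter_by_significance(eoad, config$significance_threshold)
    load_ <- filter_by_significance(load_, config$significance_threshold)
    ov <- overlap_summary(eoad, load_)
    emit(tibble(set = c("EOAD_total", "LOAD_total", "EOAD_exclusive",
                        "LOAD_exclusive", "shared"),
                n = c(ov$n_a, ov$n_b, ov$n_exclusive_a, ov$n_exclusive_b,
                      ov$n_shared)),
         "overlap.tsv")
    chr_tbl <- dplyr::full_join(
      chromosome_distribution(eoad) %>% dplyr::rename(eoad = n),
      chromosome_distribution(load_) %>% dplyr::rename(load = n),
      by = "chromosome")
    emit(chr_tbl, "chromosome_distribution.tsv")
    csq_tbl <- dplyr::full_join(
      consequence_table(eoad) %>% dplyr::rename(eoad = n),
      consequence_table(load_) %>% dplyr::rename(load = n),
      by = "consequence")
    emit(csq_tbl, "consequence_table.tsv")
    emit(serialize_variants(top_variants(eoad, 10)), "top_variants_eoad.tsv")
    emit(serialize_variants(top_variants(load_, 10)), "top_variants_load.tsv")
    emit(gene_recurrence(eoad), "gene_recurrence_eoad.tsv")
    emit(gene_recurrence(load_), "gene_recurrence_load.tsv")

    stage <- "integrate"
    if (!dir.exists(config$egenes_dir)) {
      stop("egenes directory not found: ", config$egenes_dir)
    }
    files <- egenes_files(config)
    files <- files[names(files) %in% config$tissues]
    panel <- lapply(seq_along(files),
                    function(i) read_egenes(files[i], names(files)[i]))
    index <- build_match_index(panel)
    records <- match_variants(bind_rows(eoad, load_), index,
                              config$qval_threshold)
    emit(records, "eqtl_records.tsv")

    stage <- "slopes"
    profiles <- regulatory_profiles(records)
    emit(profiles[, setdiff(names(profiles), c("tissues", "slopes"))],
         "slope_profiles.tsv")
    emit(slope_long_table(records), "slope_long.tsv")

    stage <- "cluster"
    n_clustered <- 0L
    for (nm in names(config$tpm)) {
      m <- read_expression_matrix(config$tpm[[nm]])
      if (ncol(m) >= 2) {
        dend <- hierarchical_cluster(m, axis = "columns")
        emit(dend$merges, paste0("cluster_", nm, "_merges.tsv"))
        emit(tibble(leaf = dend$leaf_order),
             paste0("cluster_", nm, "_leaf_order.tsv"))
        n_clustered <- n_clustered + 1L
      }
    }

    stage <- "network"
    network_counts <- list()
    for (nm in names(config$edges)) {
      g <- read_edge_list(config$edges[[nm]], config$min_confidence)
      gs <- graph_summary(g)
      emit(gs$nodes, paste0("network_", nm, "_nodes.tsv"))
      emit(tibble(metric = c("n_nodes", "n_edges", "average_degree",
                             "mean_local_clustering"),
                  value = c(gs$n_nodes, gs$n_edges, gs$average_degree,
                            gs$mean_local_clustering)),
           paste0("network_", nm, "_summary.tsv"))
      network_counts[[nm]] <- c(nodes = gs$n_nodes, edges = gs$n_edges)
      if (!is.null(config$annotation)) {
        ann <- read_tsv_raw(config$annotation)
        enr <- term_enrichment(gs$nodes$node, ann, config$background_n)
        emit(enr, paste0("enrichment_", nm, ".tsv"))
      }
    }

    stage <- "manifest"
    inputs <- c(config$gwas_eoad, config$gwas_load, files,
                config$tpm, config$edges, config$annotation)
    manifest$inputs <- lapply(
      setNames(as.character(inputs), basename(as.character(inputs))),
      function(p) unname(tools::md5sum(p)))
    manifest$counts <- list(
      eoad_variants = nrow(eoad),
      load_variants = nrow(load_),
      total_variants = ov$n_a + ov$n_b,
      distinct_variants = ov$n_a + ov$n_b - ov$n_shared,
      shared_variants = ov$n_shared,
      egenes_files = length(files),
      indexed_rsids = length(index),
      eqtl_records = nrow(records),
      eoad_records = sum(records$group == "EOAD"),
      load_records = sum(records$group == "LOAD"),
      profiled_genes = nrow(profiles),
      multi_tissue_genes = sum(profiles$n_tissues >= 2),
      clustered_matrices = n_clustered,
      networks = network_counts
    )
    path <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, path)
    manifest
  }, error = function(e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

# flatten the mapped_genes list column for TSV output
serialize_variants <- function(variants) {
  variants$mapped_genes <- vapply(variants$mapped_genes, paste, "",
                                  collapse = ", ")
  variants
}
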