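# Synthetic-data generation with planted, exactly recoverable structure:
# GWAS groups with controlled overlap, per-tissue egenes panels carrying
# planted GWAS<->eQTL matches, cluster-structured TPM matrices and modular
# protein networks. Background egenes rsIDs live in a reserved namespace
# (rs9xxxxxxxx) so they can never collide with simulated GWAS rsIDs.

.rsid_background_base <- 900000000L

#' Configuration for the synthetic-data generator
#'
#' Bundles and validates every knob the generator honours. Defaults
#' reproduce the scale of the EOAD/LOAD case study: 32 early-onset and
#' 255 late-onset variants with 6 shared, autosome-only placement, the
#' pooled consequence-class mix of the case-study tables, and the
#' 13-tissue CNS + whole-blood panel.
#'
#' @param seed integer RNG seed; every generator draws from a stream
#'   derived from it, so a fixed seed gives byte-identical output.
#' @param n_eoad,n_load,n_shared group sizes and the exact number of
#'   rsIDs shared between the groups (`n_shared <= min(n_eoad, n_load)`).
#' @param chromosome_weights named probability vector over chromosomes
#'   1-22 (sex chromosomes are not simulated: the case study observed no
#'   variants there); must sum to 1 within 1e-9.
#' @param consequence_probs named probability vector over the nine
#'   consequence classes; must sum to 1 within 1e-9.
#' @param p_value_range `(min, max)` for log-uniform p-value sampling;
#'   `max` must sit below the 1e-5 significance threshold so every
#'   simulated variant is study-eligible.
#' @param tissues tissue label vector for the egenes panel.
#' @param planted_matches tibble (`rsid`, `gene_name`, `tissue`, `slope`)
#'   of GWAS-matchable lead eQTLs to plant; every planted rsID must appear
#'   in at least one generated GWAS group, which the generator guarantees
#'   by injecting planted rsIDs into the EOAD/LOAD rsID pools.
#' @param planted_in which group receives each planted rsID: `"EOAD"` or
#'   `"LOAD"` (recycled).
#' @param n_background_egenes decoy lead-eQTL rows per tissue, with rsIDs
#'   from the reserved `rs9xxxxxxxx` namespace.
#' @param tpm_n_genes number of genes in the simulated TPM matrix.
#' @param tpm_cluster_spec list of tissue clusters, each
#'   `list(tissues = <labels>, mean = <TPM>, sd = <noise sd>)`; cluster
#'   means must be non-negative.
#' @param ppi_modules list of network modules, each
#'   `list(nodes = <labels>, density = <edge probability>)`; module node
#'   sets must be disjoint.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_eoad = 32L, n_load = 255L, n_shared = 6L,
                              chromosome_weights = NULL,
                              consequence_probs = NULL,
                              p_value_range = c(1e-30, 9.9e-6),
                              tissues = tissue_panel(),
                              planted_matches = NULL,
                              planted_in = "LOAD",
                              n_background_egenes = 50L,
                              tpm_n_genes = 20L,
                              tpm_cluster_spec = NULL,
                              ppi_modules = NULL) {
  if (is.null(chromosome_weights)) {
    chromosome_weights <- setNames(rep(1 / 22, 22), as.character(1:22))
  }
  if (is.null(consequence_probs)) {
    # pooled consequence mix of the case-study variant set (n = 287)
    counts <- c(`3_prime_utr` = 6, downstream_gene = 13, intergenic = 92,
                intron = 126, missense = 18, non_coding_transcript_exon = 9,
                regulatory_region = 3, synonymous = 3, upstream_gene = 17)
    consequence_probs <- counts / sum(counts)
  }
  if (is.null(planted_matches)) {
    planted_matches <- tibble(rsid = character(), gene_name = character(),
                              tissue = character(), slope = double())
  }
  if (is.null(tpm_cluster_spec)) {
    half <- ceiling(length(tissues) / 2)
    tpm_cluster_spec <- list(
      list(tissues = tissues[seq_len(half)], mean = 5, sd = 1),
      list(tissues = tissues[-seq_len(half)], mean = 50, sd = 5)
    )
  }
  if (is.null(ppi_modules)) ppi_modules <- list()

  stopifnot(
    n_shared >= 0, n_shared <= min(n_eoad, n_load),
    abs(sum(chromosome_weights) - 1) < 1e-9,
    abs(sum(consequence_probs) - 1) < 1e-9,
    all(names(chromosome_weights) %in% as.character(1:22)),
    all(sort(names(consequence_probs)) == sort(.consequence_levels)),
    length(p_value_range) == 2, p_value_range[1] > 0,
    p_value_range[1] <= p_value_range[2], p_value_range[2] < 1e-5,
    !anyDuplicated(tissues),
    all(planted_matches$tissue %in% tissues)
  )
  if (anyDuplicated(planted_matches[c("gene_name", "tissue")])) {
    stop("planted gene duplicated within a tissue", call. = FALSE)
  }
  for (cl in tpm_cluster_spec) {
    if (cl$mean < 0) stop("negative TPM cluster mean", call. = FALSE)
    stopifnot(all(cl$tissues %in% tissues))
  }
  mod_nodes <- unlist(lapply(ppi_modules, `[[`, "nodes"))
  if (anyDuplicated(mod_nodes)) {
    stop("PPI module node lists must be disjoint", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), n_eoad = as.integer(n_eoad),
    n_load = as.integer(n_load), n_shared = as.integer(n_shared),
    chromosome_weights = chromosome_weights,
    consequence_probs = consequence_probs,
    p_value_range = p_value_range, tissues = tissues,
    planted_matches = as_tibble(planted_matches),
    planted_in = rep_len(planted_in, max(1, nrow(planted_matches))),
    n_background_egenes = as.integer(n_background_egenes),
    tpm_n_genes = as.integer(tpm_n_genes),
    tpm_cluster_spec = tpm_cluster_spec,
    ppi_modules = ppi_modules
  ), class = "simulation_config")
}

with_stream <- function(config, offset, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed + offset)
  expr
}

#' Generate EOAD and LOAD GWAS variant tables
#'
#' Draws `n_eoad` + `n_load` - `n_shared` distinct rsIDs and assembles two
#' groups whose sizes and shared-rsID count are *exact*, not expected
#' values. Shared variants carry identical annotation in both groups. All
#' p-values fall strictly below 1e-5 (log-uniform over `p_value_range`),
#' chromosomes and consequence classes follow the configured probability
#' vectors, and planted-match rsIDs from the config are injected so every
#' planted eQTL has a matchable GWAS variant.
#'
#' @param config a [simulation_config()].
#' @return list with elements `eoad` and `load`, each a GWAS variant
#'   tibble in [read_gwas_table()] layout.
#' @export
generate_gwas_groups <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_stream(config, 0L, {
    n_total <- config$n_eoad + config$n_load - config$n_shared
    nums <- sample(1000000:89999999, n_total)
    rsids <- paste0("rs", nums)

    planted <- unique(config$planted_matches$rsid)
    if (length(planted) > 0) {
      grp <- config$planted_in[match(planted, config$planted_matches$rsid)]
      # overwrite the head of each group's exclusive pool with planted ids
      excl_eoad <- if (config$n_eoad > config$n_shared)
        (config$n_shared + 1):config$n_eoad else integer(0)
      excl_load <- if (n_total > config$n_eoad)
        (config$n_eoad + 1):n_total else integer(0)
      i_e <- 0L; i_l <- 0L
      for (j in seq_along(planted)) {
        if (grp[j] == "EOAD") {
          i_e <- i_e + 1L
          if (i_e > length(excl_eoad)) stop("more planted EOAD rsIDs than exclusive EOAD slots", call. = FALSE)
          rsids[excl_eoad[i_e]] <- planted[j]
        } else {
          i_l <- i_l + 1L
          if (i_l > length(excl_load)) stop("more planted LOAD rsIDs than exclusive LOAD slots", call. = FALSE)
          rsids[excl_load[i_l]] <- planted[j]
        }
      }
    }

    annotate <- function(ids, group) {
      k <- length(ids)
      lo <- log10(config$p_value_range[1])
      hi <- log10(config$p_value_range[2])
      genes <- sprintf("SYNG%05d", match(ids, rsids))
      pair <- runif(k) < 0.15
      mapped <- lapply(seq_len(k), function(i) {
        if (pair[i]) c(genes[i], paste0(genes[i], "B")) else genes[i]
      })
      tibble(
        rsid = ids,
        chromosome = sample(names(config$chromosome_weights), k,
                            replace = TRUE, prob = config$chromosome_weights),
        position = sample.int(200000000L, k, replace = TRUE),
        p_value = 10^runif(k, lo, hi),
        mapped_genes = mapped,
        consequence = sample(names(config$consequence_probs), k,
                             replace = TRUE, prob = config$consequence_probs),
        group = group
      )
    }

    shared_ids <- rsids[seq_len(config$n_shared)]
    eoad_ids <- rsids[seq_len(config$n_eoad)]
    load_ids <- c(shared_ids, rsids[seq(config$n_eoad + 1, n_total)])

    eoad <- annotate(eoad_ids, "EOAD")
    load <- annotate(load_ids, "LOAD")
    # shared variants keep one annotation across groups
    if (config$n_shared > 0) {
      load[match(shared_ids, load$rsid), setdiff(names(load), "group")] <-
        eoad[match(shared_ids, eoad$rsid), setdiff(names(eoad), "group")]
    }
    list(eoad = eoad, load = load)
  })
}

#' Generate a per-tissue lead cis-eQTL panel with planted matches
#'
#' Emulates GTEx-style `egenes` tables: for each tissue, one row per gene.
#' Planted (rsid, gene, tissue, slope) rows appear exactly once with the
#' stated slope and a q-value below the 0.05 eGene convention; background
#' decoy rows carry reserved-namespace rsIDs (`rs9xxxxxxxx`) guaranteed
#' absent from any generated GWAS group, so exact-rsID matching recovers
#' the planted set with neither false positives nor false negatives.
#'
#' @param config a [simulation_config()].
#' @return named list, tissue -> egenes tibble ([read_egenes()] layout).
#' @export
generate_egenes_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_stream(config, 1L, {
    counter <- 0L
    panel <- lapply(seq_along(config$tissues), function(ti) {
      tis <- config$tissues[ti]
      nb <- config$n_background_egenes
      bg_ids <- sprintf("rs%d", .rsid_background_base + counter + seq_len(nb))
      counter <<- counter + nb
      bg <- tibble(
        gene_id = sprintf("ENSGSYN%02d%04d.1", ti, seq_len(nb)),
        gene_name = sprintf("BG%02d_%04d", ti, seq_len(nb)),
        rs_id = bg_ids,
        pval_nominal = 10^runif(nb, -12, -6),
        qval = runif(nb, 0, 0.04),
        slope = rnorm(nb, 0, 0.5),
        tissue = tis
      )
      planted <- config$planted_matches[config$planted_matches$tissue == tis, ]
      if (nrow(planted) > 0) {
        if (any(planted$gene_name %in% bg$gene_name)) {
          stop("planted gene duplicated within a tissue", call. = FALSE)
        }
        bg <- bind_rows(tibble(
          gene_id = sprintf("ENSGPLT%02d%04d.1", ti, seq_len(nrow(planted))),
          gene_name = planted$gene_name,
          rs_id = planted$rsid,
          pval_nominal = 1e-8,
          qval = 0.01,
          slope = planted$slope,
          tissue = tis
        ), bg)
      }
      bg
    })
    names(panel) <- config$tissues
    panel
  })
}

#' Generate a cluster-structured TPM matrix
#'
#' Tissues inside a declared cluster share one expected TPM level; i.i.d.
#' Gaussian noise with the cluster's s.d. is added and draws are truncated
#' at zero (TPM is non-negative). With s.d. 0 the matrix holds the exact
#' cluster means.
#'
#' @param config a [simulation_config()] with at least two tissues across
#'   its `tpm_cluster_spec`.
#' @return numeric genes x tissues matrix.
#' @export
generate_tpm_matrix <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  tissues <- unlist(lapply(config$tpm_cluster_spec, `[[`, "tissues"))
  if (length(tissues) < 2) stop("need at least 2 tissues", call. = FALSE)
  with_stream(config, 2L, {
    genes <- sprintf("GENE%03d", seq_len(config$tpm_n_genes))
    m <- matrix(0, length(genes), length(tissues),
                dimnames = list(genes, tissues))
    for (cl in config$tpm_cluster_spec) {
      vals <- rnorm(length(genes) * length(cl$tissues), cl$mean, cl$sd)
      m[, cl$tissues] <- pmax(0, vals)
    }
    m
  })
}

#' Generate a modular protein interaction graph
#'
#' Each configured module places an edge between every within-module node
#' pair independently with the module's density; density 1 gives a
#' complete subgraph, density 0 an edgeless one. No cross-module edges are
#' generated, so disjoint modules come out as separate connected
#' components. Edge confidences are drawn uniformly from \[0.4, 1\].
#'
#' @param config a [simulation_config()] with `ppi_modules`.
#' @return an undirected simple igraph graph with a `confidence` edge
#'   attribute.
#' @export
generate_ppi <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_stream(config, 3L, {
    nodes <- unlist(lapply(config$ppi_modules, `[[`, "nodes"))
    edges <- list()
    for (mod in config$ppi_modules) {
      if (length(mod$nodes) < 2) next
      pairs <- utils::combn(sort(mod$nodes), 2)
      keep <- runif(ncol(pairs)) < mod$density
      if (mod$density >= 1) keep <- rep(TRUE, ncol(pairs))
      if (any(keep)) {
        edges[[length(edges) + 1]] <- data.frame(
          from = pairs[1, keep], to = pairs[2, keep],
          confidence = round(runif(sum(keep), 0.4, 1), 3),
          stringsAsFactors = FALSE
        )
      }
    }
    el <- if (length(edges) > 0) do.call(rbind, edges) else
      data.frame(from = character(), to = character(),
                 confidence = double(), stringsAsFactors = FALSE)
    igraph::graph_from_data_frame(el, directed = FALSE,
                                  vertices = sort(unique(nodes)))
  })
}

#' Write a complete simulated input bundle
#'
#' Materialises one simulation as the on-disk formats the pipeline reads:
#' `gwas_eoad.tsv`, `gwas_load.tsv`, an `egenes/` directory with one
#' GTEx-dialect file per tissue, `tpm_matrix.tsv`, `ppi_edges.tsv` and a
#' JSON echo of the configuration. Output is deterministic: a fixed seed
#' yields byte-identical files.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation_bundle <- function(config, dir) {
  dir.create(file.path(dir, "egenes"), recursive = TRUE, showWarnings = FALSE)
  groups <- generate_gwas_groups(config)
  write_gwas_table(groups$eoad, file.path(dir, "gwas_eoad.tsv"))
  write_gwas_table(groups$load, file.path(dir, "gwas_load.tsv"))
  panel <- generate_egenes_panel(config)
  for (tis in names(panel)) {
    write_egenes(panel[[tis]],
                 file.path(dir, "egenes", paste0(tis, ".v8.egenes.txt")))
  }
  write_expression_matrix(generate_tpm_matrix(config),
                          file.path(dir, "tpm_matrix.tsv"))
  if (length(config$ppi_modules) > 0) {
    write_edge_list(generate_ppi(config), file.path(dir, "ppi_edges.tsv"))
  }
  cfg <- config[c("seed", "n_eoad", "n_load", "n_shared", "tissues",
                  "n_background_egenes", "tpm_n_genes")]
  jsonlite::write_json(cfg, file.path(dir, "simulation_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
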