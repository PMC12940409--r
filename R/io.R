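# Tabular IO: GWAS association tables, GTEx-format egenes tables, TPM
# expression matrices, and confidence-scored edge lists. All formats are
# tab-separated with a header, UTF-8; gzip input is detected by magic bytes
# (gzfile() reads plain files transparently).

read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  read.delim(con, sep = "\t", header = TRUE, quote = "",
             check.names = FALSE, colClasses = "character",
             na.strings = character())
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

write_tsv_plain <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a GWAS association table
#'
#' Parses a tab-separated GWAS table with columns `rsid`, `chromosome`,
#' `position`, `p_value`, `mapped_genes` and `consequence`. rsIDs are
#' normalized ([normalize_rsid()]); chromosome labels are stripped of any
#' `chr` prefix and validated against 1-22/X/Y; `mapped_genes` may hold a
#' comma-separated list (intergenic variants carry their two flanking
#' genes). Rows with malformed rsIDs, unparseable or out-of-range p-values
#' (p must lie in (0, 1]), or invalid chromosome labels are dropped with a
#' warning naming the row; a missing required column is fatal.
#'
#' @param path path to a plain or gzipped TSV file.
#' @param group_label trait group to stamp on every variant, `"EOAD"` or
#'   `"LOAD"`.
#' @return a tibble with one row per variant: `rsid`, `chromosome`,
#'   `position`, `p_value`, `mapped_genes` (list column of character
#'   vectors), `consequence` (canonical token) and `group`.
#' @seealso [write_gwas_table()], [read_egenes()]
#' @export
read_gwas_table <- function(path, group_label) {
  group_label <- match.arg(group_label, c("EOAD", "LOAD"))
  df <- read_tsv_raw(path)
  required <- c("rsid", "chromosome", "position", "p_value",
                "mapped_genes", "consequence")
  require_columns(df, required, path)
  if (nrow(df) == 0) {
    return(tibble(
      rsid = character(), chromosome = character(), position = integer(),
      p_value = double(), mapped_genes = list(),
      consequence = character(), group = character()
    ))
  }

  rsid <- normalize_rsid(df$rsid)
  bad_rsid <- !is_valid_rsid(rsid)
  if (any(bad_rsid)) {
    warning(sum(bad_rsid), " row(s) dropped: malformed rsID (",
            paste(head(unique(df$rsid[bad_rsid]), 3), collapse = ", "), ")",
            call. = FALSE)
  }

  p <- suppressWarnings(as.numeric(df$p_value))
  bad_p <- is.na(p) | p <= 0 | p > 1
  if (any(bad_p & !bad_rsid)) {
    warning(sum(bad_p & !bad_rsid),
            " row(s) dropped: unparseable or out-of-range p-value",
            call. = FALSE)
  }

  chrom <- normalize_chromosome(df$chromosome)
  bad_chr <- is.na(chrom)
  if (any(bad_chr & !bad_rsid & !bad_p)) {
    warning(sum(bad_chr & !bad_rsid & !bad_p),
            " row(s) dropped: chromosome label outside 1-22/X/Y",
            call. = FALSE)
  }

  keep <- !(bad_rsid | bad_p | bad_chr)
  genes <- lapply(strsplit(df$mapped_genes[keep], ","), trimws)
  genes <- lapply(genes, function(g) g[nzchar(g)])

  tibble(
    rsid = rsid[keep],
    chromosome = chrom[keep],
    position = as.integer(suppressWarnings(as.numeric(df$position[keep]))),
    p_value = p[keep],
    mapped_genes = genes,
    consequence = normalize_consequence(df$consequence[keep]),
    group = group_label
  )
}

#' Write a GWAS association table
#'
#' Inverse of [read_gwas_table()]; the `mapped_genes` list column is
#' serialized as a comma-separated field and the `group` column is not
#' written (it is supplied again at read time).
#'
#' @param variants tibble as returned by [read_gwas_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_gwas_table <- function(variants, path) {
  out <- data.frame(
    rsid = variants$rsid,
    chromosome = variants$chromosome,
    position = variants$position,
    p_value = format(variants$p_value, digits = 15, trim = TRUE),
    mapped_genes = vapply(variants$mapped_genes, paste, "", collapse = ", "),
    consequence = variants$consequence,
    stringsAsFactors = FALSE
  )
  write_tsv_plain(out, path)
}

#' Read a GTEx-format lead cis-eQTL ("egenes") table
#'
#' Parses one tissue's `egenes` file in the GTEx v8 column dialect. The
#' five fields the pipeline uses are `gene_id`, `gene_name`,
#' `rs_id_dbSNP151_GRCh38p7`, `pval_nominal`, `slope` and `qval`; any
#' further GTEx columns are ignored. Each row is one gene's single most
#' significant cis regulatory variant in that tissue; duplicate `gene_id`
#' rows are resolved by keeping the smallest `pval_nominal` (ties: smallest
#' `qval`, then lexicographically smallest rsID). Rows whose slope is not
#' numeric are dropped with a warning. The rsID sentinel `"."` (variant
#' without a dbSNP identifier) is retained but never matched downstream.
#'
#' @param path plain or gzipped TSV (gzip detected by magic bytes, so the
#'   file extension does not matter).
#' @param tissue_label tissue to stamp on every row.
#' @return tibble with columns `gene_id`, `gene_name`, `rs_id`,
#'   `pval_nominal`, `qval`, `slope`, `tissue`.
#' @seealso [write_egenes()], [build_match_index()]
#' @export
read_egenes <- function(path, tissue_label) {
  df <- read_tsv_raw(path)
  required <- c("gene_id", "gene_name", "rs_id_dbSNP151_GRCh38p7",
                "pval_nominal", "slope", "qval")
  require_columns(df, required, path)

  slope <- suppressWarnings(as.numeric(df$slope))
  bad_slope <- is.na(slope) & nrow(df) > 0
  if (any(bad_slope)) {
    warning(sum(bad_slope), " row(s) dropped: non-numeric slope",
            call. = FALSE)
  }

  out <- tibble(
    gene_id = df$gene_id,
    gene_name = df$gene_name,
    rs_id = normalize_rsid(df$rs_id_dbSNP151_GRCh38p7),
    pval_nominal = suppressWarnings(as.numeric(df$pval_nominal)),
    qval = suppressWarnings(as.numeric(df$qval)),
    slope = slope,
    tissue = tissue_label
  )[!bad_slope, ]

  # one lead eQTL per gene per tissue
  out %>%
    arrange(gene_id, pval_nominal, qval, rs_id) %>%
    distinct(gene_id, .keep_all = TRUE)
}

#' Write an egenes table in the GTEx column dialect
#'
#' @param egenes tibble as returned by [read_egenes()].
#' @param path output TSV path (a `.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_egenes <- function(egenes, path) {
  out <- data.frame(
    gene_id = egenes$gene_id,
    gene_name = egenes$gene_name,
    rs_id_dbSNP151_GRCh38p7 = egenes$rs_id,
    pval_nominal = format(egenes$pval_nominal, digits = 15, trim = TRUE),
    slope = format(egenes$slope, digits = 15, trim = TRUE),
    qval = format(egenes$qval, digits = 15, trim = TRUE),
    stringsAsFactors = FALSE
  )
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "wt")
    on.exit(close(con))
    write.table(out, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    return(invisible(path))
  }
  write_tsv_plain(out, path)
}

#' Read and write TPM expression matrices
#'
#' The on-disk format is a TSV whose first column (`gene`) holds gene
#' symbols and whose remaining columns hold per-tissue TPM values.
#' Duplicate gene rows and negative TPM values are fatal (TPM is
#' non-negative by construction). `write_expression_matrix()` is the exact
#' inverse up to floating-point formatting.
#'
#' @param path TSV path.
#' @return a numeric matrix with gene rownames and tissue colnames.
#' @examples
#' m <- matrix(c(0, 1, 3, 7), 2, dimnames = list(c("A", "B"), c("t1", "t2")))
#' f <- tempfile(fileext = ".tsv")
#' write_expression_matrix(m, f)
#' all.equal(read_expression_matrix(f), m)
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv_raw(path)
  if (ncol(df) < 2) stop("expression matrix needs a gene column plus >= 1 tissue",
                         call. = FALSE)
  genes <- df[[1]]
  if (anyDuplicated(genes)) {
    stop("duplicate gene row(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- vapply(df[-1], function(col) suppressWarnings(as.numeric(col)),
                 numeric(nrow(df)))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(genes, names(df)[-1]))
  if (anyNA(vals)) stop("non-numeric TPM value", call. = FALSE)
  if (any(vals < 0)) stop("negative TPM value", call. = FALSE)
  vals
}

#' @rdname read_expression_matrix
#' @param m non-negative numeric matrix (genes x tissues).
#' @export
write_expression_matrix <- function(m, path) {
  if (any(m < 0)) stop("negative TPM value", call. = FALSE)
  fm <- format(m, digits = 15, trim = TRUE)
  out <- data.frame(gene = rownames(m), fm,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c("gene", colnames(m))
  write_tsv_plain(out, path)
}

#' Read a confidence-scored protein interaction edge list
#'
#' Parses a TSV whose first three columns are the two interacting proteins
#' and an interaction confidence score in \[0, 1\] (STRING-style combined
#' scores divided by 1000). Edges below `min_confidence` are excluded --
#' the conventional medium-confidence cut-off is 0.4. Self-loops are
#' dropped with a warning and duplicate edges (either orientation)
#' collapse to a single undirected edge keeping the highest confidence.
#' The node set is taken from *all* rows, so filtering never removes a
#' protein, only its edges.
#'
#' @param path TSV path.
#' @param min_confidence minimum confidence score to retain an edge.
#' @return an undirected simple [igraph::igraph] graph with a `confidence`
#'   edge attribute.
#' @seealso [graph_summary()]
#' @export
read_edge_list <- function(path, min_confidence = 0.4) {
  df <- read_tsv_raw(path)
  if (ncol(df) < 3) stop("edge list needs columns: node A, node B, confidence",
                         call. = FALSE)
  a <- trimws(df[[1]])
  b <- trimws(df[[2]])
  conf <- suppressWarnings(as.numeric(df[[3]]))
  if (anyNA(conf) && nrow(df) > 0) stop("non-numeric confidence score", call. = FALSE)

  loops <- a == b
  if (any(loops)) {
    warning(sum(loops), " self-loop row(s) dropped", call. = FALSE)
  }
  nodes <- sort(unique(c(a, b)))
  keep <- !loops & conf >= min_confidence
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[keep], to = b[keep], confidence = conf[keep],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = nodes
  )
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(confidence = "max"))
}

#' Write a protein interaction edge list
#'
#' @param graph undirected igraph graph with a `confidence` edge attribute.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  conf <- igraph::edge_attr(graph, "confidence")
  if (is.null(conf)) conf <- rep(1, nrow(el))
  out <- data.frame(node_a = el[, 1], node_b = el[, 2],
                    confidence = format(conf, digits = 15, trim = TRUE),
                    stringsAsFactors = FALSE)
  out <- out[order(out$node_a, out$node_b), , drop = FALSE]
  write_tsv_plain(out, path)
}
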