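# Basal-expression profiling: TPM transformation and hierarchical
# clustering of tissues/genes into heatmap orderings and dendrograms.

#' Log-transform a TPM matrix
#'
#' Elementwise `log2(TPM + 1)`, the standard variance-stabilising
#' transform for heatmap display of non-negative expression values. Shape
#' and dimnames are preserved. Pass the identity via
#' `hierarchical_cluster(..., transform = identity)` when raw-TPM
#' clustering is wanted.
#'
#' @param m non-negative numeric matrix (genes x tissues).
#' @return transformed matrix.
#' @examples
#' transform_tpm(matrix(c(0, 1, 3, 7), 2)) # 0, 1, 2, 3
#' @export
transform_tpm <- function(m) {
  if (any(m < 0)) stop("TPM values must be non-negative", call. = FALSE)
  log2(m + 1)
}

#' Hierarchically cluster an expression matrix
#'
#' Clusters tissues (columns) or genes (rows) of a TPM matrix, by default
#' on `log2(TPM + 1)` values with Euclidean distance and average linkage.
#' Input labels are sorted before distances are computed, so the result is
#' invariant to the order in which rows/columns arrive; among equidistant
#' merge candidates this fixes the tie-break to the lexicographically
#' smallest label pair.
#'
#' @param m numeric expression matrix with unique dimnames.
#' @param axis cluster `"columns"` (tissues; default) or `"rows"` (genes).
#' @param metric distance metric passed to [stats::dist()].
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @param transform matrix transform applied first; default
#'   [transform_tpm()], use `identity` for raw values.
#' @return an object of class `dendro` wrapping the [stats::hclust()] tree:
#'   `hclust`, `labels`, `leaf_order` (labels in dendrogram order), and
#'   `merges`, a tibble (`child1`, `child2`, `height`, `size`) whose
#'   children name leaves directly and internal nodes as `"cluster_<k>"`.
#' @seealso [cut_dendro()], [heatmap_values()]
#' @export
hierarchical_cluster <- function(m, axis = c("columns", "rows"),
                                 metric = "euclidean", linkage = "average",
                                 transform = transform_tpm) {
  axis <- match.arg(axis)
  x <- transform(m)
  if (axis == "columns") x <- t(x)
  if (nrow(x) < 2) stop("need at least 2 labels on the clustered axis",
                        call. = FALSE)
  if (is.null(rownames(x)) || anyDuplicated(rownames(x))) {
    stop("clustered axis must carry unique labels", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("non-finite values in expression matrix",
                               call. = FALSE)
  x <- x[order(rownames(x)), , drop = FALSE]
  h <- hclust(dist(x, method = metric), method = linkage)

  lab_of <- function(idx) {
    out <- character(length(idx))
    leaf <- idx < 0
    out[leaf] <- h$labels[-idx[leaf]]
    out[!leaf] <- paste0("cluster_", idx[!leaf])
    out
  }
  sizes <- integer(nrow(h$merge))
  for (k in seq_len(nrow(h$merge))) {
    sz <- function(i) if (i < 0) 1L else sizes[i]
    sizes[k] <- sz(h$merge[k, 1]) + sz(h$merge[k, 2])
  }
  merges <- tibble(
    child1 = lab_of(h$merge[, 1]),
    child2 = lab_of(h$merge[, 2]),
    height = h$height,
    size = sizes
  )
  structure(
    list(hclust = h, labels = h$labels,
         leaf_order = h$labels[h$order], merges = merges),
    class = "dendro"
  )
}

#' @export
print.dendro <- function(x, ...) {
  cat("Hierarchical clustering of", length(x$labels), "labels;",
      "leaf order:", paste(x$leaf_order, collapse = ", "), "\n")
  invisible(x)
}

#' Cut a dendrogram into k groups
#'
#' @param dendro a `dendro` object from [hierarchical_cluster()].
#' @param k number of groups.
#' @return named integer vector of group memberships ([stats::cutree()]).
#' @export
cut_dendro <- function(dendro, k) {
  stopifnot(inherits(dendro, "dendro"))
  cutree(dendro$hclust, k = k)
}

#' Values exported to the heatmap
#'
#' Returns exactly the transformed matrix the clustering ran on, reordered
#' to the dendrogram leaf order -- no silent rescaling, so heatmap cell
#' values equal the transformed data.
#'
#' @param m the expression matrix handed to [hierarchical_cluster()].
#' @param dendro_cols,dendro_rows optional `dendro` objects ordering
#'   columns and/or rows.
#' @param transform the same transform used for clustering.
#' @return the transformed, reordered matrix.
#' @export
heatmap_values <- function(m, dendro_cols = NULL, dendro_rows = NULL,
                           transform = transform_tpm) {
  x <- transform(m)
  if (!is.null(dendro_cols)) x <- x[, dendro_cols$leaf_order, drop = FALSE]
  if (!is.null(dendro_rows)) x <- x[dendro_rows$leaf_order, , drop = FALSE]
  x
}

#' Draw an expression heatmap (convenience)
#'
#' Best-effort plotting wrapper around `pheatmap`; the analysis surface is
#' [hierarchical_cluster()] / [heatmap_values()], and plotting changes no
#' computed value.
#'
#' @param m non-negative TPM matrix.
#' @param transform transform applied before display.
#' @param ... passed to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly.
#' @export
plot_expression_heatmap <- function(m, transform = transform_tpm, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_expression_heatmap() needs the 'pheatmap' package",
         call. = FALSE)
  }
  invisible(pheatmap::pheatmap(
    transform(m),
    clustering_distance_rows = "euclidean",
    clustering_distance_cols = "euclidean",
    clustering_method = "average",
    ...
  ))
}
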