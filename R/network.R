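# Protein-network topology statistics, interaction-count enrichment
# against an explicit null, and hypergeometric term enrichment with
# Benjamini-Hochberg FDR control.

#' Topology summary of a protein interaction network
#'
#' Computes the node count, edge count, average node degree (2E/N) and
#' local clustering coefficients of a simple undirected graph. The local
#' clustering coefficient of a node v with degree k and T triangles
#' through it is 2T / (k (k - 1)); nodes of degree < 2 are assigned 0
#' (their neighbourhood cannot close a triangle).
#'
#' @param graph simple undirected [igraph::igraph] graph.
#' @return object of class `graph_summary`: `n_nodes`, `n_edges`,
#'   `average_degree`, `mean_local_clustering`, and `nodes`, a per-node
#'   tibble (`node`, `degree`, `triangles`, `clustering`).
#' @examples
#' g <- igraph::make_full_graph(6)
#' graph_summary(g)$n_edges # 15
#' @export
graph_summary <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::is_directed(graph) || !igraph::is_simple(graph)) {
    stop("graph must be simple and undirected", call. = FALSE)
  }
  n <- igraph::vcount(graph)
  e <- igraph::ecount(graph)
  a <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  deg <- rowSums(a)
  triangles <- diag(a %*% a %*% a) / 2
  clustering <- ifelse(deg < 2, 0, 2 * triangles / (deg * (deg - 1)))
  node_names <- igraph::V(graph)$name
  if (is.null(node_names)) node_names <- as.character(seq_len(n))
  structure(list(
    n_nodes = n,
    n_edges = e,
    average_degree = if (n > 0) 2 * e / n else 0,
    mean_local_clustering = if (n > 0) mean(clustering) else 0,
    nodes = tibble(node = node_names, degree = as.integer(deg),
                   triangles = as.integer(round(triangles)),
                   clustering = as.numeric(clustering))
  ), class = "graph_summary")
}

#' @export
print.graph_summary <- function(x, ...) {
  cat("Network:", x$n_nodes, "nodes,", x$n_edges, "edges\n")
  cat("  average degree        :", format(x$average_degree, digits = 4), "\n")
  cat("  mean local clustering :",
      format(x$mean_local_clustering, digits = 4), "\n")
  invisible(x)
}

#' Interaction-count enrichment against a Poisson null
#'
#' Upper-tail probability of observing at least `observed` interactions
#' when `expected` are expected by chance, with the edge count modelled as
#' Poisson(expected). This is an explicit, reproducible null standing in
#' for database-specific background models (whose expected counts are
#' version- and background-dependent); it approximates, and is not an
#' exact replica of, such tests.
#'
#' @param observed non-negative integer count of observed edges.
#' @param expected positive expected edge count under the null (e.g. from
#'   [expected_edges_er()]).
#' @return the p-value `P(X >= observed)`.
#' @examples
#' interaction_enrichment(15, 6) # ~8e-4
#' @export
interaction_enrichment <- function(observed, expected) {
  if (observed < 0) stop("observed edge count must be >= 0", call. = FALSE)
  stopifnot(expected > 0)
  ppois(observed - 1, lambda = expected, lower.tail = FALSE)
}

#' Expected edge count under an Erdos-Renyi background
#'
#' `choose(n, 2) * density`: the expected number of edges among `n`
#' proteins when each pair interacts independently with the background
#' density.
#'
#' @param n number of nodes.
#' @param density background interaction probability in \[0, 1\].
#' @return expected edge count.
#' @export
expected_edges_er <- function(n, density) {
  stopifnot(density >= 0, density <= 1, n >= 0)
  choose(n, 2) * density
}

#' Hypergeometric gene-set over-representation with BH-FDR
#'
#' For every annotation term, tests whether the query gene set overlaps
#' the term's gene set more than expected when drawing `length(query)`
#' genes without replacement from a background of `background_n`
#' annotatable genes: p = P(X >= k) with X hypergeometric(K, N - K, n).
#' Benjamini-Hochberg adjustment is applied across all tested terms.
#'
#' @param query_genes character vector of query gene symbols (deduplicated
#'   internally); must be no larger than the background.
#' @param annotation term-to-gene mapping: either a named list of gene
#'   vectors or a tibble/data.frame with columns `term` and `gene`.
#' @param background_n number of annotatable background genes; every term
#'   must fit inside it.
#' @return tibble sorted by p (ties by term id): `term`, `overlap`,
#'   `term_size`, `query_size`, `background`, `p`, `fdr`.
#' @examples
#' ann <- list(T1 = c("A", "B", "C"), T2 = c("D", "E"))
#' term_enrichment(c("A", "B"), ann, background_n = 10)
#' @export
term_enrichment <- function(query_genes, annotation, background_n) {
  if (is.data.frame(annotation)) {
    annotation <- split(annotation$gene, annotation$term)
  }
  annotation <- lapply(annotation, unique)
  query <- unique(query_genes)
  n <- length(query)
  if (n > background_n) {
    stop("query is larger than the background", call. = FALSE)
  }
  sizes <- lengths(annotation)
  if (any(sizes > background_n)) {
    stop("term(s) larger than the background: ",
         paste(names(annotation)[sizes > background_n], collapse = ", "),
         call. = FALSE)
  }
  if (length(annotation) == 0) {
    return(tibble(term = character(), overlap = integer(),
                  term_size = integer(), query_size = integer(),
                  background = integer(), p = double(), fdr = double()))
  }
  k <- vapply(annotation, function(g) length(intersect(query, g)), 0L)
  p <- phyper(k - 1, sizes, background_n - sizes, n, lower.tail = FALSE)
  out <- tibble(
    term = names(annotation),
    overlap = as.integer(k),
    term_size = as.integer(sizes),
    query_size = as.integer(n),
    background = as.integer(background_n),
    p = as.numeric(p),
    fdr = p.adjust(p, method = "BH")
  )
  out[order(out$p, out$term), ]
}
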