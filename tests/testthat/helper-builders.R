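# Shared in-code builders for small test inputs.

variants_tbl <- function(rsid, chromosome = "1", p_value = 1e-8,
                         genes = NULL, consequence = "intron",
                         group = "EOAD") {
  n <- length(rsid)
  if (is.null(genes)) genes <- as.list(sprintf("G%02d", seq_len(n)))
  if (!is.list(genes)) genes <- as.list(genes)
  tibble::tibble(
    rsid = rsid,
    chromosome = rep_len(as.character(chromosome), n),
    position = seq_len(n) * 1000L,
    p_value = rep_len(p_value, n),
    mapped_genes = genes,
    consequence = rep_len(consequence, n),
    group = rep_len(group, n)
  )
}

egenes_tbl <- function(gene_name, rs_id, tissue, slope = 0.5,
                       pval_nominal = 1e-8, qval = 0.01) {
  n <- length(gene_name)
  tibble::tibble(
    gene_id = sprintf("ENSGT%04d.1", seq_len(n)),
    gene_name = gene_name,
    rs_id = rs_id,
    pval_nominal = rep_len(pval_nominal, n),
    qval = rep_len(qval, n),
    slope = rep_len(slope, n),
    tissue = rep_len(tissue, n)
  )
}

write_lines_tsv <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# brute-force local clustering coefficient by direct neighbour-pair
# counting, independent of the adjacency-matrix implementation
clustering_bruteforce <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    closed <- 0L
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (adj[nb[i], nb[j]] == 1) closed <- closed + 1L
      }
    }
    2 * closed / (k * (k - 1))
  }, 0)
}

# exhaustive hypergeometric upper tail: enumerate every possible query
# draw of size n from a background of size N and count overlaps >= k
hyper_tail_enum <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K) # genes 1..K are "in the term"
  mean(hits >= k)
}
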