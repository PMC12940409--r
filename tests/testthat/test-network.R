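test_that("graph summary: complete, sparse and path graphs", {
  k6 <- igraph::make_full_graph(6)
  igraph::V(k6)$name <- LETTERS[1:6]
  s <- graph_summary(k6)
  expect_equal(s$n_edges, 15)
  expect_equal(s$average_degree, 5)
  expect_equal(s$mean_local_clustering, 1)

  p3 <- igraph::make_graph(~ A - B, B - C)
  expect_equal(graph_summary(p3)$mean_local_clustering, 0) # no triangles

  g916 <- igraph::sample_gnm(9, 16)
  igraph::V(g916)$name <- LETTERS[1:9]
  expect_equal(graph_summary(g916)$average_degree, 32 / 9)
  expect_equal(round(graph_summary(g916)$average_degree, 2), 3.56)
})

test_that("average degree times N equals 2E on random graphs", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    g <- igraph::sample_gnp(n, runif(1))
    s <- graph_summary(g)
    expect_equal(s$average_degree * s$n_nodes, 2 * s$n_edges)
    expect_true(s$mean_local_clustering >= 0 &&
                  s$mean_local_clustering <= 1)
  }
})

test_that("local clustering agrees with igraph and brute force on random graphs", {
  set.seed(8)
  for (i in 1:10) {
    n <- sample(4:9, 1)
    g <- igraph::sample_gnp(n, 0.5)
    s <- graph_summary(g)
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    expect_equal(s$nodes$clustering, clustering_bruteforce(adj))
    ig <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    expect_equal(s$nodes$clustering, ig)
  }
})

test_that("interaction enrichment is the Poisson upper tail", {
  expect_equal(interaction_enrichment(0, 6), 1) # P(X >= 0) = 1
  # brute-force partial sum oracle: 1 - sum_{x<15} e^-6 6^x / x!
  brute <- 1 - sum(exp(-6) * 6^(0:14) / factorial(0:14))
  expect_equal(interaction_enrichment(15, 6), brute, tolerance = 1e-12)
  expect_equal(interaction_enrichment(15, 6), 0.001400354,
               tolerance = 1e-6)
  # observed equal to a large expectation sits near 1/2 (normal sanity)
  expect_equal(interaction_enrichment(400, 400), 0.5, tolerance = 0.05)
  expect_error(interaction_enrichment(-1, 6))
})

test_that("Erdos-Renyi expected edge counts", {
  expect_equal(expected_edges_er(6, 0.4), 6)
  expect_equal(expected_edges_er(10, 0), 0)
  expect_equal(expected_edges_er(9, 0.1667), 36 * 0.1667)
})

test_that("hypergeometric enrichment: degenerate and closed-form cases", {
  # zero overlap is never enriched
  r0 <- term_enrichment(c("X", "Y"), list(T1 = c("A", "B")), 10)
  expect_equal(r0$p, 1)
  # query == term == background: the overlap is certain
  r1 <- term_enrichment(LETTERS[1:5],
                        list(ALL = LETTERS[1:5]), 5)
  expect_equal(r1$p, 1)
  # N=20, K=5, n=5, k=5: probability 1 / C(20,5)
  r2 <- term_enrichment(LETTERS[1:5], list(T = LETTERS[1:5]), 20)
  expect_equal(r2$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(r2$overlap, 5)
  expect_error(term_enrichment(LETTERS[1:5],
                               list(BIG = LETTERS[1:10]), 8), "larger")
})

test_that("hypergeometric p agrees with exhaustive enumeration for small N", {
  # enumerate every C(N, n) query draw and count overlaps >= k
  cases <- expand.grid(N = c(8, 10, 12), K = c(3, 5), n = c(3, 6))
  for (i in seq_len(nrow(cases))) {
    N <- cases$N[i]; K <- cases$K[i]; n <- cases$n[i]
    genes <- sprintf("g%02d", seq_len(N))
    term <- list(T = genes[seq_len(K)])
    k_min <- max(0, n - (N - K)) # need n - k genes outside the term
    for (k_in_query in k_min:min(K, n)) {
      outside <- if (k_in_query < n)
        genes[(K + 1):(K + n - k_in_query)] else character()
      query <- c(genes[seq_len(k_in_query)], outside)
      got <- term_enrichment(query, term, N)$p
      want <- hyper_tail_enum(k_in_query, K, N, n)
      expect_equal(got, want, tolerance = 1e-12,
                   label = sprintf("N=%d K=%d n=%d k=%d", N, K, n,
                                   k_in_query))
    }
  }
})

test_that("BH adjustment is monotone over sorted p and order-invariant", {
  ann <- list(
    T1 = sprintf("g%d", 1:4), T2 = sprintf("g%d", 3:8),
    T3 = sprintf("g%d", 1:2), T4 = sprintf("g%d", 7:12),
    T5 = sprintf("g%d", 5:6)
  )
  q <- sprintf("g%d", 1:5)
  r <- term_enrichment(q, ann, 30)
  expect_true(all(diff(r$fdr[order(r$p)]) >= -1e-12))
  r_rev <- term_enrichment(q, rev(ann), 30)
  expect_equal(r[order(r$term), ], r_rev[order(r_rev$term), ])
  # results sorted by p with term-id tie-break
  expect_equal(r$p, sort(r$p))
})
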