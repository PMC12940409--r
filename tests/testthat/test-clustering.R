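test_that("the TPM transform is exact log2(TPM + 1)", {
  m <- matrix(c(0, 1, 3, 7), 2, 2,
              dimnames = list(c("g1", "g2"), c("t1", "t2")))
  expect_equal(transform_tpm(m),
               matrix(c(0, 1, 2, 3), 2, 2,
                      dimnames = dimnames(m)))
  expect_error(transform_tpm(matrix(-1)), "non-negative")
})

test_that("average-linkage merges match the brute-force 1-D oracle", {
  # points {0, 1, 10}: first merge {0,1} at height 1; then the average
  # distance from 10 to {0,1} is (10 + 9) / 2 = 9.5
  m <- matrix(c(0, 1, 10), 3, 1, dimnames = list(c("a", "b", "c"), "x"))
  d <- hierarchical_cluster(m, axis = "rows", transform = identity)
  expect_equal(d$merges$height, c(1, 9.5))
  expect_equal(sort(c(d$merges$child1[1], d$merges$child2[1])),
               c("a", "b"))
  expect_equal(d$merges$size, c(2L, 3L))
})

test_that("identical rows merge first at height zero", {
  m <- matrix(c(1, 1, 5, 2, 2, 9), 3, 2,
              dimnames = list(c("r1", "r2", "r3"), c("c1", "c2")))
  d <- hierarchical_cluster(m, axis = "rows", transform = identity)
  expect_equal(d$merges$height[1], 0)
  expect_equal(sort(c(d$merges$child1[1], d$merges$child2[1])),
               c("r1", "r2"))
})

test_that("clustering is invariant to input row order", {
  set.seed(11)
  m <- matrix(rnorm(8 * 4, 10, 3), 8, 4,
              dimnames = list(sprintf("g%02d", 1:8), sprintf("t%d", 1:4)))
  m <- abs(m)
  d1 <- hierarchical_cluster(m, axis = "rows")
  perm <- sample(nrow(m))
  d2 <- hierarchical_cluster(m[perm, ], axis = "rows")
  expect_equal(d1$leaf_order, d2$leaf_order)
  expect_equal(d1$merges, d2$merges)
})

test_that("merge heights are monotone and leaves cover the labels", {
  set.seed(3)
  m <- abs(matrix(rnorm(6 * 5, 20, 5), 6, 5,
                  dimnames = list(sprintf("g%d", 1:6),
                                  sprintf("t%d", 1:5))))
  d <- hierarchical_cluster(m, axis = "columns")
  expect_true(all(diff(d$merges$height) >= -1e-12))
  expect_equal(sort(d$leaf_order), sort(colnames(m)))
})

test_that("planted two-cluster structure is recovered exactly at the root", {
  cfg <- simulation_config(seed = 19, tpm_n_genes = 10,
                           tpm_cluster_spec = list(
                             list(tissues = tissue_panel()[1:6],
                                  mean = 1, sd = 0.1),
                             list(tissues = tissue_panel()[7:13],
                                  mean = 100, sd = 0.1)))
  m <- generate_tpm_matrix(cfg)
  d <- hierarchical_cluster(m, axis = "columns")
  groups <- cut_dendro(d, 2)
  planted <- ifelse(names(groups) %in% tissue_panel()[1:6], 1, 2)
  # membership must agree up to label swapping
  expect_true(all(table(groups, planted) %in%
                    c(0, table(planted)[1], table(planted)[2])))
  expect_equal(length(unique(groups[tissue_panel()[1:6]])), 1)
  expect_equal(length(unique(groups[tissue_panel()[7:13]])), 1)
})

test_that("cophenetic distance bounds the pointwise metric under single linkage", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(3:6, 1)
    m <- abs(matrix(rnorm(n * 3, 5, 2), n, 3,
                    dimnames = list(sprintf("g%d", 1:n), c("a", "b", "c"))))
    d <- hierarchical_cluster(m, axis = "rows", linkage = "single",
                              transform = identity)
    pointwise <- as.matrix(dist(m[order(rownames(m)), ]))
    coph <- as.matrix(cophenetic(d$hclust))
    coph <- coph[rownames(pointwise), colnames(pointwise)]
    # single linkage: merge height is the *minimum* inter-cluster
    # distance, so cophenetic distances never exceed the pointwise ones
    expect_true(all(coph <= pointwise + 1e-9))
  }
})

test_that("heatmap export equals the transformed matrix with no rescaling", {
  m <- matrix(c(0, 1, 3, 7, 15, 31), 2, 3,
              dimnames = list(c("g1", "g2"), c("t1", "t2", "t3")))
  d <- hierarchical_cluster(m, axis = "columns")
  h <- heatmap_values(m, dendro_cols = d)
  expect_equal(sort(colnames(h)), sort(colnames(m)))
  expect_equal(h[, d$leaf_order[1]], transform_tpm(m)[, d$leaf_order[1]])
  expect_equal(unname(heatmap_values(m)), unname(log2(m + 1)))
})

test_that("degenerate clustering inputs are fatal", {
  m1 <- matrix(1:4, 1, 4, dimnames = list("g1", sprintf("t%d", 1:4)))
  expect_error(hierarchical_cluster(m1, axis = "rows"), "at least 2")
  m2 <- matrix(c(1, NA, 2, 3), 2, 2,
               dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(hierarchical_cluster(m2, axis = "rows",
                                    transform = identity), "non-finite")
})
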