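test_that("severity ranking picks the most severe annotation", {
  # rank-order oracle: the declared severity list, most severe first
  declared <- c("missense", "synonymous", "3_prime_utr",
                "non_coding_transcript_exon", "intron", "upstream_gene",
                "downstream_gene", "regulatory_region", "intergenic")
  expect_equal(names(sort(consequence_severity())), declared)

  expect_equal(assign_most_severe(c("intron", "missense")), "missense")
  expect_equal(assign_most_severe(c("upstream_gene", "downstream_gene")),
               "upstream_gene")
  expect_equal(assign_most_severe("intergenic"), "intergenic")
  # every suffix of the severity list resolves to its head
  for (i in seq_along(declared)) {
    expect_equal(assign_most_severe(declared[i:length(declared)]),
                 declared[i])
  }
  expect_error(assign_most_severe(character()), "empty")
  expect_error(normalize_consequence("frameshift"), "frameshift")
})

test_that("significance filtering is strict at the threshold", {
  v <- variants_tbl(c("rs1", "rs2", "rs3"),
                    p_value = c(3e-15, 1e-5, 9.9e-6))
  kept <- filter_by_significance(v, 1e-5)
  expect_equal(kept$rsid, c("rs1", "rs3")) # exactly 1e-5 is dropped
  expect_equal(nrow(filter_by_significance(v[0, ], 1e-5)), 0)
  expect_error(filter_by_significance(v, 0))
})

test_that("chromosome distribution reports all labels with zeros", {
  v <- variants_tbl("rs1", chromosome = "19")
  d <- chromosome_distribution(v)
  expect_equal(nrow(d), 24)
  expect_equal(sum(d$n), 1)
  expect_equal(d$n[d$chromosome == "19"], 1)
  expect_equal(d$n[d$chromosome %in% c("X", "Y")], c(0, 0))
})

test_that("overlap summary partitions by rsID and is symmetric", {
  a <- variants_tbl(c("rs1", "rs2", "rs3"))
  b <- variants_tbl(c("rs2", "rs3", "rs4", "rs5"), group = "LOAD")
  ov <- overlap_summary(a, b)
  expect_equal(ov$n_exclusive_a, 1)
  expect_equal(ov$n_exclusive_b, 2)
  expect_equal(ov$shared, c("rs2", "rs3"))
  expect_true(length(intersect(ov$exclusive_a, ov$shared)) == 0)
  expect_equal(ov$n_a, ov$n_exclusive_a + ov$n_shared)

  sw <- overlap_summary(b, a)
  expect_equal(sw$exclusive_a, ov$exclusive_b)
  expect_equal(sw$exclusive_b, ov$exclusive_a)
  expect_equal(sw$shared, ov$shared)

  expect_equal(overlap_summary(a, a)$n_shared, 3)
  dis <- overlap_summary(a, variants_tbl("rs9", group = "LOAD"))
  expect_equal(c(dis$n_exclusive_a, dis$n_exclusive_b, dis$n_shared),
               c(3, 1, 0))
})

test_that("duplicate rsIDs within a group are counted once, keeping smallest p", {
  v <- variants_tbl(c("rs1", "rs1", "rs2"), p_value = c(1e-6, 1e-9, 1e-7))
  expect_warning(d <- chromosome_distribution(v), "dedup")
  expect_equal(sum(d$n), 2)
  expect_warning(t1 <- top_variants(v, 1), "dedup")
  expect_equal(t1$p_value, 1e-9)
})

test_that("consequence table always covers the nine classes and sums to n", {
  v <- variants_tbl(c("rs1", "rs2", "rs3"),
                    consequence = c("intron", "intron", "missense"))
  tab <- consequence_table(v)
  expect_equal(nrow(tab), 9)
  expect_equal(sum(tab$n), 3)
  expect_equal(tab$n[tab$consequence == "intron"], 2)
  expect_equal(sum(consequence_table(v[0, ])$n), 0)
})

test_that("gene recurrence collapses order-reversed multi-gene annotations", {
  v <- variants_tbl(c("rs1", "rs2", "rs3"),
                    genes = list(c("ADAMTS2", "U4"), c("U4", "ADAMTS2"),
                                 "NBEA"))
  r <- gene_recurrence(v)
  expect_equal(r$n[r$gene_label == "ADAMTS2, U4"], 2)
  expect_equal(r$n[r$gene_label == "NBEA"], 1)
  allu <- gene_recurrence(variants_tbl(c("rs4", "rs5")))
  expect_true(all(allu$n == 1))
})

test_that("top variants rank by p with lexicographic rsID tie-break", {
  v <- variants_tbl(c("rs20", "rs10", "rs3"),
                    chromosome = c("1", "1", "2"),
                    p_value = c(1e-8, 1e-8, 1e-12))
  t2 <- top_variants(v, 2)
  expect_equal(t2$rsid, c("rs3", "rs10"))
  expect_equal(top_variants(v, 99)$rsid, c("rs3", "rs10", "rs20"))
  per <- top_variants(v, 1, per_chromosome = TRUE)
  expect_equal(per$rsid, c("rs10", "rs3"))
})

test_that("filtering commutes with the chromosome distribution", {
  set.seed(42)
  v <- variants_tbl(sprintf("rs%d", 1:50),
                    chromosome = sample(as.character(1:22), 50, TRUE),
                    p_value = 10^runif(50, -12, -2))
  f <- filter_by_significance(v, 1e-5)
  expect_equal(chromosome_distribution(f),
               chromosome_distribution(v[v$p_value < 1e-5, ]))
  expect_equal(sum(chromosome_distribution(f)$n), nrow(f))
  expect_equal(sum(consequence_table(f)$n), nrow(f))
})
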