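test_that("generated group sizes and overlap are exact, not expected", {
  for (seed in c(1, 17)) {
    cfg <- simulation_config(seed = seed, n_eoad = 32, n_load = 255,
                             n_shared = 6)
    g <- generate_gwas_groups(cfg)
    expect_equal(nrow(g$eoad), 32)
    expect_equal(nrow(g$load), 255)
    expect_equal(length(intersect(g$eoad$rsid, g$load$rsid)), 6)
    expect_true(all(c(g$eoad$p_value, g$load$p_value) < 1e-5))
    expect_false(anyDuplicated(g$eoad$rsid) > 0)
  }
  dis <- generate_gwas_groups(simulation_config(seed = 2, n_eoad = 10,
                                                n_load = 20, n_shared = 0))
  expect_equal(length(intersect(dis$eoad$rsid, dis$load$rsid)), 0)
  expect_error(simulation_config(n_eoad = 5, n_load = 20, n_shared = 6))
})

test_that("a fixed seed reproduces the GWAS tables exactly", {
  cfg <- simulation_config(seed = 11)
  expect_identical(generate_gwas_groups(cfg), generate_gwas_groups(cfg))
})

test_that("egenes panel plants each match exactly once with its slope", {
  pm <- tibble::tibble(
    rsid = c("rs111", "rs222"),
    gene_name = c("GENEA", "GENEB"),
    tissue = c("Brain_Cortex", "Whole_Blood"),
    slope = c(0.42, -0.13)
  )
  cfg <- simulation_config(seed = 5, planted_matches = pm,
                           planted_in = c("EOAD", "LOAD"))
  panel <- generate_egenes_panel(cfg)
  expect_equal(names(panel), tissue_panel())
  combined <- dplyr::bind_rows(panel)
  hit <- combined[combined$rs_id == "rs111", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$tissue, "Brain_Cortex")
  expect_equal(hit$slope, 0.42)
  # background decoys live in the reserved rs9 namespace and never
  # collide with generated GWAS rsIDs
  bg <- combined[!(combined$rs_id %in% pm$rsid), ]
  expect_true(all(grepl("^rs9[0-9]{8}$", bg$rs_id)))
  g <- generate_gwas_groups(cfg)
  expect_equal(length(intersect(bg$rs_id, c(g$eoad$rsid, g$load$rsid))), 0)
  # one row per gene per tissue
  for (tis in names(panel)) {
    expect_false(anyDuplicated(panel[[tis]]$gene_name) > 0)
  }
})

test_that("planted gene duplicated within a tissue is fatal", {
  pm <- tibble::tibble(rsid = c("rs1", "rs2"),
                       gene_name = c("GENEA", "GENEA"),
                       tissue = c("Brain_Cortex", "Brain_Cortex"),
                       slope = c(0.1, 0.2))
  expect_error(simulation_config(planted_matches = pm), "duplicated")
})

test_that("TPM generation honours cluster means, truncation and shape", {
  spec0 <- list(list(tissues = tissue_panel()[1:3], mean = 7, sd = 0),
                list(tissues = tissue_panel()[4:5], mean = 2, sd = 0))
  cfg <- simulation_config(seed = 3, tpm_n_genes = 4,
                           tpm_cluster_spec = spec0)
  m <- generate_tpm_matrix(cfg)
  expect_equal(dim(m), c(4, 5))
  expect_true(all(m[, 1:3] == 7)) # sd 0: exact cluster means
  expect_true(all(m[, 4:5] == 2))

  noisy <- simulation_config(seed = 3, tpm_n_genes = 50,
                             tpm_cluster_spec = list(
                               list(tissues = tissue_panel()[1:4],
                                    mean = 0.01, sd = 1)))
  expect_true(all(generate_tpm_matrix(noisy) >= 0)) # truncated at zero

  one <- simulation_config(seed = 3, tpm_n_genes = 1,
                           tpm_cluster_spec = spec0)
  expect_equal(nrow(generate_tpm_matrix(one)), 1)
  expect_error(simulation_config(tpm_cluster_spec = list(
    list(tissues = tissue_panel()[1:2], mean = -1, sd = 0))), "negative")
})

test_that("PPI modules obey density: complete, empty, disconnected", {
  full <- simulation_config(seed = 9, ppi_modules = list(
    list(nodes = LETTERS[1:6], density = 1)))
  g <- generate_ppi(full)
  expect_equal(igraph::ecount(g), choose(6, 2)) # 15
  expect_true(igraph::is_simple(g))

  none <- simulation_config(seed = 9, ppi_modules = list(
    list(nodes = LETTERS[1:6], density = 0)))
  expect_equal(igraph::ecount(generate_ppi(none)), 0)

  two <- simulation_config(seed = 9, ppi_modules = list(
    list(nodes = LETTERS[1:4], density = 1),
    list(nodes = LETTERS[5:9], density = 1)))
  expect_equal(igraph::count_components(generate_ppi(two)), 2)

  expect_error(simulation_config(ppi_modules = list(
    list(nodes = c("A", "B"), density = 1),
    list(nodes = c("B", "C"), density = 1))), "disjoint")
})

test_that("a fixed seed yields byte-identical simulation bundles", {
  cfg <- simulation_config(seed = 21, n_eoad = 8, n_load = 15,
                           n_shared = 2, n_background_egenes = 5,
                           tissues = tissue_panel()[1:3],
                           ppi_modules = list(list(nodes = LETTERS[1:5],
                                                   density = 0.6)))
  d1 <- file.path(withr::local_tempdir(), "b1")
  d2 <- file.path(withr::local_tempdir(), "b2")
  write_simulation_bundle(cfg, d1)
  write_simulation_bundle(cfg, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_equal(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
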