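test_that("default design has the full factorial layout", {
  d <- gen_design()
  expect_equal(nrow(d), 24L)
  expect_setequal(unique(d$treatment), c("CC", "UC", "CW", "UW"))
  expect_equal(unname(table(d$treatment)), rep(6L, 4), ignore_attr = TRUE)
  expect_equal(sum(d$warming), 12L)
  expect_equal(sum(d$clipping), 12L)
  expect_false(anyDuplicated(d$sample_id) > 0)
  # every block contains every treatment exactly once at defaults
  expect_true(all(table(d$block, d$treatment) == 1L))
})

test_that("gen_design scales with n_reps and validates input", {
  d <- gen_design(n_reps = 20L)
  expect_equal(nrow(d), 80L)
  expect_equal(unname(table(d$treatment)), rep(20L, 4), ignore_attr = TRUE)
  expect_error(gen_design(n_blocks = 0), "n_blocks")
  expect_error(gen_design(n_reps = -1), "n_reps")
})

test_that("synth_params validates its arguments", {
  expect_error(synth_params(n_pao_taxa = 500L, n_taxa = 300L), "n_pao_taxa")
  expect_error(synth_params(frac_competitors = 1.5), "frac_competitors")
  expect_error(synth_params(frac_antagonists = -0.1), "frac_antagonists")
  p <- synth_params(seed = 7L)
  expect_equal(p$n_taxa, 300L)
  expect_equal(p$n_pao_taxa, 150L)
  expect_equal(p$seed, 7L)
})

test_that("gen_otu_table is deterministic with planted structure", {
  d <- gen_design()
  p <- synth_params(seed = 3L)
  g1 <- gen_otu_table(d, p)
  g2 <- gen_otu_table(d, p)
  expect_identical(g1$table$counts, g2$table$counts)

  tab <- g1$table
  expect_s3_class(tab, "pao_otu_table")
  expect_equal(n_taxa(tab), p$n_taxa)
  expect_equal(n_samples(tab), 24L)
  expect_equal(unname(colSums(tab$counts)), rep(p$depth, 24))
  expect_length(g1$truth$pao_taxa, p$n_pao_taxa)
  expect_true(all(g1$truth$pao_taxa %in% rownames(tab$counts)))
  expect_named(g1$truth$h_fun_target, d$sample_id)
})

test_that("planted quality flaws appear at the requested rates", {
  d <- gen_design()
  p <- synth_params(seed = 5L)
  g <- gen_otu_table(d, p)
  genus <- extract_genus(g$table$taxonomy)
  frac_nogenus <- mean(is.na(genus))
  frac_lowe <- mean(g$table$e_score < 99)
  expect_gt(frac_nogenus, 0)
  expect_lt(abs(frac_nogenus - p$frac_no_genus), 0.05)
  expect_gt(frac_lowe, 0)
  expect_lt(abs(frac_lowe - p$frac_low_escore), 0.05)
})

test_that("gen_function_table plants the four marker genes on PAOs", {
  d <- gen_design()
  p <- synth_params(seed = 2L)
  g <- gen_otu_table(d, p)
  fn <- gen_function_table(g$table, p)
  genes <- fn$genes
  expect_setequal(colnames(genes), c("ppk1", "ppx", "phaZ", "phaC"))
  full <- rowSums(genes) == 4L
  # every planted PAO carries all four genes; bulk taxa do not
  expect_true(all(full[g$truth$pao_taxa]))
  bulk <- setdiff(rownames(genes), g$truth$pao_taxa)
  expect_false(any(full[bulk]))
  expect_true(all(fn$contrib >= 0))
})

test_that("gen_spectra produces the full cell panel with archetype labels", {
  d <- gen_design()
  p <- synth_params(seed = 1L, cells_per_drop = 5L)
  sp <- gen_spectra(d, params = p)
  expect_s3_class(sp, "spectra_set")
  n_cells <- 24L * p$n_drops * p$cells_per_drop
  expect_equal(ncol(sp$intensities), n_cells)
  expect_equal(nrow(sp$meta), n_cells)
  expect_true(all(sp$meta$archetype %in% seq_len(7)))
  expect_true(all(sp$meta$sample_id %in% d$sample_id))
  expect_true(min(sp$wavenumbers) <= 406 && max(sp$wavenumbers) >= 1994)
})

test_that("gen_env links warming to the planted environmental shifts", {
  d <- gen_design()
  env <- gen_env(d, synth_params(seed = 4L, env_noise = 0))
  warm <- env$sample_id %in% d$sample_id[d$warming == 1]
  expect_gt(mean(env$soil_t[warm]), mean(env$soil_t[!warm]))
  expect_lt(mean(env$tp[warm]), mean(env$tp[!warm]))
  expect_gt(mean(env$ap[warm]), mean(env$ap[!warm]))
  expect_true(all(env$loi >= 0 & env$loi <= 100))
})

test_that("gen_coupling_panel couples the two metric panels as requested", {
  p1 <- gen_coupling_panel(200L, coupling = 1, seed = 11L)
  p0 <- gen_coupling_panel(200L, coupling = 0, seed = 11L)
  r1 <- cor(p1$complexity[[1]], p1$stability[[1]])
  r0 <- cor(p0$complexity[[1]], p0$stability[[1]])
  expect_gt(r1, 0.5)
  expect_lt(abs(r0), 0.3)
  expect_identical(gen_coupling_panel(24L, seed = 2L),
                   gen_coupling_panel(24L, seed = 2L))
})

test_that("write_synthetic writes readable text artifacts", {
  d <- gen_design()
  p <- synth_params(seed = 6L, n_taxa = 40L, n_pao_taxa = 20L, depth = 500L)
  g <- gen_otu_table(d, p)
  dir <- tempfile("synth_")
  paths <- write_synthetic(dir, design = d, otu = g$table, truth = g$truth)
  expect_true(all(file.exists(paths)))
  rt <- read_otu_tsv(paths[["otu_table.tsv"]])
  expect_equal(rt$counts, g$table$counts)
  expect_equal(rt$e_score, g$table$e_score, tolerance = 1e-9)
})
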