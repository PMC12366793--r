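make_table <- function() {
  counts <- matrix(c(5000L, 4000L, 3000L, 2000L,
                     5000L, 4000L, 3000L, 2000L,
                     5000L, 4000L, 3000L, 2000L,
                     1L,    0L,    1L,    0L),
                   nrow = 4, byrow = TRUE,
                   dimnames = list(c("A", "B", "C", "rare"),
                                   sprintf("s%d", 1:4)))
  # "rare" fails both the abundance and the e-score rule: the ledger must
  # attribute it to abundance (fixed rule order)
  otu_table(counts,
            taxonomy = c(A = "k__X;g__Alpha;s__a", B = "k__X;g__Beta;s__b",
                         C = "k__X;g__", rare = "k__X;g__Gamma;s__c"),
            e_score = c(A = 100, B = 95, C = 100, rare = 95))
}

test_that("filter_otus applies all three rules with the fixed reason order", {
  tab <- make_table()
  out <- filter_otus(tab)
  expect_equal(rownames(out$counts), "A")
  removed <- attr(out, "removed")
  expect_setequal(removed$taxon, c("B", "C", "rare"))
  expect_equal(removed$reason[removed$taxon == "B"], "escore")
  expect_equal(removed$reason[removed$taxon == "C"], "genus")
  # abundance failure outranks any other reason
  expect_equal(removed$reason[removed$taxon == "rare"], "abundance")
})

test_that("filter_otus recovers exactly the clean planted taxa", {
  d <- gen_design()
  p <- synth_params(seed = 8L)
  g <- gen_otu_table(d, p)
  out <- filter_otus(g$table)
  genus <- extract_genus(g$table$taxonomy)
  rel <- paoscope:::mean_relative_abundance(g$table)
  expected <- rownames(g$table$counts)[
    rel >= 1e-4 & g$table$e_score >= 99 & !is.na(genus)]
  expect_setequal(rownames(out$counts), expected)
})

test_that("require_pao_genes keeps only four-gene taxa and validates input", {
  d <- gen_design()
  p <- synth_params(seed = 9L)
  g <- gen_otu_table(d, p)
  fn <- gen_function_table(g$table, p)
  filt <- filter_otus(g$table)
  pao <- require_pao_genes(filt, fn)
  keep <- rownames(fn$genes)[rowSums(fn$genes) == 4L]
  expect_setequal(rownames(pao$counts), intersect(rownames(filt$counts), keep))

  fn_missing <- fn
  fn_missing$genes <- fn$genes[-1, , drop = FALSE]
  broken <- filt
  expect_error(require_pao_genes(broken, fn_missing), "missing")
  fn_cols <- fn
  colnames(fn_cols$genes)[1] <- "ppk2"
  expect_error(require_pao_genes(filt, fn_cols), "gene columns")
})

test_that("enrichment_efficiency flags taxa absent from the bulk", {
  counts_s <- matrix(c(80L, 20L, 10L, 90L), 2,
                     dimnames = list(c("A", "B"), c("s1", "s2")))
  counts_b <- matrix(c(50L, 0L, 50L, 0L), 2,
                     dimnames = list(c("A", "B"), c("s1", "s2")))
  sorted <- otu_table(counts_s, c(A = "g__A", B = "g__B"), c(A = 100, B = 100))
  bulk <- otu_table(counts_b, c(A = "g__A", B = "g__B"), c(A = 100, B = 100))
  eff <- enrichment_efficiency(sorted, bulk)
  expect_equal(eff$efficiency[eff$taxon == "A"],
               mean(c(0.8, 0.1)) / 1, tolerance = 1e-12)
  expect_true(is.infinite(eff$efficiency[eff$taxon == "B"]))
  expect_true(eff$absent_in_bulk[eff$taxon == "B"])
})

test_that("pool_replicates conserves counts and never mixes treatments", {
  d <- gen_design()
  p <- synth_params(seed = 10L, n_taxa = 50L, n_pao_taxa = 25L, depth = 1000L)
  g <- gen_otu_table(d, p)
  pooled <- pool_replicates(g$table, d, k_pools = 3L, seed = 1L)
  expect_equal(ncol(pooled$table$counts), 12L)
  expect_equal(sum(pooled$table$counts), sum(g$table$counts))
  for (i in seq_len(nrow(pooled$design))) {
    members <- strsplit(pooled$design$members[i], ",")[[1]]
    trts <- d$treatment[match(members, d$sample_id)]
    expect_equal(unique(trts), pooled$design$treatment[i])
    expect_equal(unname(rowSums(g$table$counts[, members, drop = FALSE])),
                 unname(pooled$table$counts[, pooled$design$sample_id[i]]))
  }
  expect_error(pool_replicates(g$table, d, k_pools = 4L), "divisible")
})

test_that("relative_abundance columns sum to one", {
  tab <- make_table()
  rel <- relative_abundance(tab)
  expect_equal(unname(colSums(rel)), rep(1, 4), tolerance = 1e-12)
})
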