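# A tiny synthetic spectra fixture: three well-separated Gaussian peak
# profiles on the native 1 cm-1 grid, `per` cells each, with mild noise.
toy_spectra <- function(per = 6L, noise = 0.01, seed = 42L) {
  wn <- 400:2000
  peak <- function(centers) {
    rowSums(vapply(centers, function(c0) exp(-((wn - c0) / 15)^2),
                   numeric(length(wn))))
  }
  shapes <- list(peak(c(600, 1500)), peak(c(900, 1200)), peak(c(700, 1700)))
  paoscope:::with_seed(seed, {
    Y <- do.call(cbind, lapply(seq_along(shapes), function(k) {
      vapply(seq_len(per), function(i) {
        shapes[[k]] + rnorm(length(wn), 0, noise)
      }, numeric(length(wn)))
    }))
  })
  Y[Y < 0] <- 0
  meta <- data.frame(cell_id = sprintf("c%02d", seq_len(ncol(Y))),
                     sample_id = rep(c("s1", "s2"), length.out = ncol(Y)),
                     group = rep(seq_along(shapes), each = per))
  spectra_set(wn, Y, meta)
}

test_that("preprocess_spectra bins, floors, and unit-normalizes", {
  sp <- toy_spectra()
  pre <- preprocess_spectra(sp)
  expect_equal(nrow(pre$intensities), 267L)   # 266 full bins + 1 partial
  expect_true(all(pre$intensities >= 0))
  expect_equal(unname(colSums(pre$intensities^2)),
               rep(1, ncol(pre$intensities)), tolerance = 1e-9)
  expect_true(isTRUE(attr(pre, "preprocessed")))
})

test_that("the ALS baseline hugs the lower envelope of a lifted spectrum", {
  wn <- 400:2000
  base <- 2 + 0.001 * (wn - 400)
  y <- base + 5 * exp(-((wn - 1000) / 10)^2)
  z <- paoscope:::als_baseline(y, lambda = 1e5, p = 0.01)
  # baseline tracks the smooth ramp away from the peak, not the peak itself
  off_peak <- abs(wn - 1000) > 100
  expect_lt(max(abs(z[off_peak] - base[off_peak])), 0.2)
  expect_lt(z[wn == 1000], y[wn == 1000] - 3)
})

test_that("quantify_biomarkers integrates a planted band and nothing else", {
  wn <- 400:2000
  y <- exp(-((wn - 695) / 2)^2)      # inside the polyp 690-700 window
  sp <- spectra_set(wn, matrix(y, ncol = 1, dimnames = list(NULL, "c1")))
  lv <- quantify_biomarkers(sp)
  expect_gt(lv["c1", "polyp"], 1)
  expect_lt(lv["c1", "pha"], 1e-6)
  expect_lt(lv["c1", "glycogen"], 1e-6)
})

test_that("confirm_pao requires all four phenotype biomarkers", {
  lv <- matrix(c(5, 5, 5, 5,
                 5, 5, 5, 0.1), nrow = 2, byrow = TRUE,
               dimnames = list(c("c1", "c2"),
                               c("peptidoglycan", "amide", "pha", "polyp")))
  out <- confirm_pao(lv, thresholds = 1)
  expect_equal(unname(out), c(TRUE, FALSE))
  out2 <- confirm_pao(lv, noise = 1)     # 3 x noise = 3
  expect_equal(unname(out2), c(TRUE, FALSE))
  expect_error(confirm_pao(lv[, 1:3]), "biomarkers")
})

test_that("cluster_opus recovers the planted groups and labels by size", {
  sp <- toy_spectra(per = 8L)
  pre <- preprocess_spectra(sp)
  cl <- cluster_opus(pre, cutoff = 0.6)
  expect_equal(length(unique(cl$assignments)), 3L)
  expect_equal(adjusted_rand_index(cl$assignments, sp$meta$group), 1,
               tolerance = 1e-12)
  expect_equal(names(cl$sizes)[1], "OPU01")
  expect_true(all(diff(as.integer(cl$sizes)) <= 0))
})

test_that("the OPU count never increases with the cutoff", {
  sp <- toy_spectra(per = 5L, noise = 0.05)
  pre <- preprocess_spectra(sp)
  ks <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(cut) {
    length(unique(cluster_opus(pre, cutoff = cut)$assignments))
  }, numeric(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("opu_abundance yields per-sample compositions summing to one", {
  sp <- toy_spectra(per = 8L)
  pre <- preprocess_spectra(sp)
  cl <- cluster_opus(pre, cutoff = 0.6)
  comp <- opu_abundance(cl)
  expect_equal(unname(rowSums(comp)), rep(1, nrow(comp)), tolerance = 1e-12)
  expect_setequal(rownames(comp), c("s1", "s2"))
})

test_that("estimate_noise tracks the injected noise level", {
  wn <- 400:2000
  set.seed(13)
  y <- sin(wn / 150) + rnorm(length(wn), 0, 0.05)
  sp <- spectra_set(wn, matrix(y, ncol = 1, dimnames = list(NULL, "c1")))
  expect_equal(unname(estimate_noise(sp)), 0.05, tolerance = 0.02)
})
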