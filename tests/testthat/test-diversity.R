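test_that("shannon matches hand-computed values", {
  expect_equal(shannon(rep(1, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon(c(7, 0, 0)), 0, tolerance = 1e-12)
  expect_equal(shannon(c(0.5, 0.25, 0.25)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)), tolerance = 1e-12)
  expect_equal(shannon(c(1, 1), base = 2), 1, tolerance = 1e-12)
  # scale invariance
  expect_equal(shannon(c(3, 2, 5)), shannon(c(30, 20, 50)), tolerance = 1e-12)
  expect_error(shannon(c(-1, 2)), "nonnegative")
  expect_error(shannon(c(0, 0)), "all-zero")
})

test_that("functional_redundancy matches its definition on hand cases", {
  contrib <- matrix(c(2, 2, 0,
                      0, 4, 0), nrow = 3,
                    dimnames = list(c("t1", "t2", "t3"), c("c1", "c2")))
  fr <- functional_redundancy(contrib)
  # c1: (2 + 2) / 2 = 2; c2: 4 / 1 = 4; mean = 3
  expect_equal(fr$per_category$fr, c(2, 4), tolerance = 1e-12)
  expect_equal(fr$fr, 3, tolerance = 1e-12)
  # linear in the contributions
  expect_equal(functional_redundancy(2 * contrib)$fr, 6, tolerance = 1e-12)
  expect_error(functional_redundancy(-contrib), "nonnegative")
})

test_that("fit_lmm recovers effects on noiseless balanced data", {
  d <- gen_design()
  y <- 1.5 * d$warming - 0.7 * d$clipping + 0.2 * d$warming * d$clipping +
    c(0.1, -0.1, 0.05, -0.05, 0, 0)[d$block]
  fm <- suppressWarnings(fit_lmm(y, d))   # noiseless fit: convergence chatter
  expect_equal(fm$term, c("warming", "clipping", "interaction"))
  expect_equal(fm$beta[fm$term == "warming"], 1.5, tolerance = 1e-6)
  expect_equal(fm$beta[fm$term == "clipping"], -0.7, tolerance = 1e-6)
  expect_equal(fm$beta[fm$term == "interaction"], 0.2, tolerance = 1e-6)
  expect_true(attr(fm, "method") %in% c("lmm", "ols"))
})

test_that("fit_lmm falls back to OLS and matches lm when blocks are inert", {
  d <- gen_design()
  set.seed(21)
  y <- 0.4 * d$warming + rnorm(24, 0, 0.5)   # no block signal: singular fit
  fm <- fit_lmm(y, d)
  if (attr(fm, "method") == "ols") {
    ref <- summary(lm(y ~ warming * clipping, data = d))$coefficients
    expect_equal(fm$beta[fm$term == "warming"], ref["warming", 1],
                 tolerance = 1e-10)
    expect_equal(fm$p[fm$term == "warming"], ref["warming", 4],
                 tolerance = 1e-10)
  }
  expect_error(fit_lmm(y[1:23], d), "length")
  d_bad <- d
  d_bad$clipping <- d_bad$warming
  expect_error(fit_lmm(y, d_bad), "rank-deficient|aliased|2 samples")
})

test_that("normal p-values are close to Satterthwaite at large df", {
  d <- gen_design(n_reps = 20L)
  set.seed(5)
  y <- 0.2 * d$warming + rnorm(6, 0, 0.2)[d$block] + rnorm(80, 0, 0.4)
  f1 <- fit_lmm(y, d, p_method = "satterthwaite")
  f2 <- fit_lmm(y, d, p_method = "normal")
  expect_equal(f1$beta, f2$beta, tolerance = 1e-12)
  expect_lt(max(abs(f1$p - f2$p)), 0.02)
})

test_that("renormalize_effects is idempotent and scale-invariant", {
  b <- c(4.097, -1.3, 0.2)
  r <- renormalize_effects(b)
  expect_equal(max(abs(r)), 1, tolerance = 1e-12)
  expect_equal(sign(r), sign(b))
  expect_equal(renormalize_effects(r), r, tolerance = 1e-12)
  expect_equal(renormalize_effects(10 * b), r, tolerance = 1e-12)
  expect_equal(renormalize_effects(c(0, 0)), c(0, 0))
})

test_that("compare_fits identifies the generating curve shape", {
  set.seed(31)
  h_tax <- runif(60, 1, 6)
  h_log <- 1.2 * log(h_tax) + rnorm(60, 0, 0.05)
  h_lin <- 0.8 * h_tax + rnorm(60, 0, 0.05)
  expect_equal(compare_fits(h_tax, h_log)$winner, "log")
  expect_equal(compare_fits(h_tax, h_lin)$winner, "linear")
  expect_error(compare_fits(c(-1, 1, 2, 3), 1:4), "positive")
})

test_that("function_profile_shannon agrees with a direct computation", {
  d <- gen_design()
  p <- synth_params(seed = 12L, n_taxa = 40L, n_pao_taxa = 20L, depth = 2000L)
  g <- gen_otu_table(d, p)
  fn <- gen_function_table(g$table, p)
  h <- function_profile_shannon(g$table, fn)
  rel <- relative_abundance(g$table)
  ref <- apply(t(fn$contrib[rownames(rel), ]) %*% rel, 2, shannon)
  expect_equal(h, ref, tolerance = 1e-12)
})
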