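test_that("percent_om implements the LOI conversion with a zero floor", {
  expect_warning(om0 <- percent_om(0), "flooring")
  expect_equal(om0, 0, tolerance = 1e-12)
  expect_equal(percent_om(10), 6.77, tolerance = 1e-12)
  expect_equal(percent_om(100), 69.77, tolerance = 1e-12)
  expect_equal(suppressWarnings(percent_om(c(0, 10))), c(0, 6.77),
               tolerance = 1e-12)
  expect_error(percent_om(-1), "LOI")
  expect_error(percent_om(101), "LOI")
})

test_that("gpp is the ER minus NEE identity", {
  expect_equal(gpp(nee = -1.2, er = 4.5), 5.7, tolerance = 1e-12)
  expect_equal(gpp(c(0, 1), c(2, 2)), c(2, 1), tolerance = 1e-12)
})

test_that("correlation_screen flags exactly the planted couple", {
  set.seed(17)
  n <- 30
  a <- rnorm(n)
  x <- data.frame(m1 = a, m2 = rnorm(n))
  y <- data.frame(f1 = 2 * a + rnorm(n, 0, 0.1), f2 = rnorm(n))
  sc <- correlation_screen(x, y, r_min = 0.6, alpha = 0.05)
  flagged <- sc$pairs[sc$pairs$significant, ]
  expect_equal(nrow(flagged), 1L)
  expect_equal(flagged$x, "m1")
  expect_equal(flagged$y, "f1")
  expect_equal(sc$n_significant, 1L)
  # r and p agree with cor.test
  ct <- cor.test(a, y$f1)
  expect_equal(flagged$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(flagged$p, ct$p.value, tolerance = 1e-12)
})

test_that("correlation_screen drops constant columns with a warning", {
  x <- data.frame(m1 = rnorm(10), flat = rep(1, 10))
  y <- data.frame(f1 = rnorm(10))
  expect_warning(sc <- correlation_screen(x, y), "constant")
  expect_false("flat" %in% sc$pairs$x)
  expect_error(correlation_screen(x[1:3, ], y[1:3, , drop = FALSE]),
               "observations")
  expect_error(correlation_screen(x, y[1:5, , drop = FALSE]), "matched")
})

test_that("the r_min boundary is inclusive and BH adjustment tightens", {
  # construct a pair with known r by mixing
  set.seed(23)
  n <- 200
  a <- rnorm(n)
  y1 <- 0.65 * a + sqrt(1 - 0.65^2) * rnorm(n)
  x <- data.frame(m = a)
  y <- data.frame(f = y1)
  r_obs <- cor(a, y1)
  sc_lo <- correlation_screen(x, y, r_min = abs(r_obs) - 1e-9)
  sc_hi <- correlation_screen(x, y, r_min = abs(r_obs) + 1e-9)
  expect_equal(sc_lo$n_significant, 1L)
  expect_equal(sc_hi$n_significant, 0L)
  sc_adj <- correlation_screen(x, y, adjust = TRUE)
  expect_lte(sc_adj$n_significant, sc_lo$n_significant)
})
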