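test_that("correlation_matrix is a valid correlation with p-values", {
  set.seed(1)
  X <- matrix(rpois(20 * 12, 40), 20, 12,
              dimnames = list(sprintf("t%02d", 1:20), sprintf("s%02d", 1:12)))
  cm <- correlation_matrix(X)
  expect_equal(cm$r, t(cm$r), tolerance = 1e-12)
  expect_equal(unname(diag(cm$r)), rep(1, nrow(cm$r)), tolerance = 1e-12)
  expect_true(all(cm$r >= -1 - 1e-12 & cm$r <= 1 + 1e-12))
  expect_true(all(cm$p >= 0 & cm$p <= 1, na.rm = TRUE))
  expect_error(correlation_matrix(X[, 1:3]), "sample")
})

test_that("build_network keeps exactly the strong significant pairs", {
  set.seed(2)
  X <- matrix(rnorm(15 * 30), 15, 30,
              dimnames = list(sprintf("t%02d", 1:15), sprintf("s%02d", 1:30)))
  X[2, ] <- X[1, ] + rnorm(30, 0, 0.1)    # one planted strong pair
  cm <- correlation_matrix(X, transform = "none")
  net <- build_network(cm, s_star = 0.8)
  el <- igraph::as_data_frame(net$graph)
  expect_true(nrow(el) >= 1)
  for (i in seq_len(nrow(el))) {
    expect_gte(abs(cm$r[el$from[i], el$to[i]]), 0.8)
    expect_lt(cm$p[el$from[i], el$to[i]], 0.05)
  }
  expect_true(any(el$from == "t01" & el$to == "t02" |
                  el$from == "t02" & el$to == "t01"))
})

test_that("nnsd_poisson_test separates GOE from Poisson spectra", {
  set.seed(3)
  n <- 200
  M <- matrix(rnorm(n * n), n)
  goe <- eigen((M + t(M)) / sqrt(2), symmetric = TRUE, only.values = TRUE)$values
  expect_lt(nnsd_poisson_test(goe)$p, 1e-6)
  pois <- cumsum(rexp(n))          # Poisson process: exponential spacings
  expect_gt(nnsd_poisson_test(pois)$p, 0.01)
  short <- nnsd_poisson_test(seq_len(10))
  expect_true(short$degenerate)
})

test_that("louvain_partition finds two planted cliques deterministically", {
  A <- matrix(0, 10, 10)
  A[1:5, 1:5] <- 1; A[6:10, 6:10] <- 1
  diag(A) <- 0
  A[5, 6] <- A[6, 5] <- 1
  dimnames(A) <- list(sprintf("t%02d", 1:10), sprintf("t%02d", 1:10))
  net <- oracle_net_from_adjacency(A)
  memb <- louvain_partition(net, seed = 1L)
  expect_equal(length(unique(memb)), 2L)
  expect_equal(length(unique(memb[1:5])), 1L)
  expect_equal(length(unique(memb[6:10])), 1L)
  expect_identical(memb, louvain_partition(net, seed = 1L))
})

test_that("vulnerability of a star is 1 (hub removal disconnects all)", {
  A <- matrix(0, 5, 5)
  A[1, 2:5] <- 1; A[2:5, 1] <- 1
  dimnames(A) <- list(sprintf("t%02d", 1:5), sprintf("t%02d", 1:5))
  expect_equal(vulnerability(oracle_net_from_adjacency(A)), 1, tolerance = 1e-12)
  # complete graph: removing any node leaves a smaller complete graph
  K <- matrix(1, 5, 5); diag(K) <- 0
  dimnames(K) <- dimnames(A)
  ek <- 1                                  # efficiency of K_n is 1 at any n
  expect_equal(vulnerability(oracle_net_from_adjacency(K)), 0, tolerance = 1e-12)
})

test_that("robustness is exact on a perfect matching", {
  # 3 disjoint edges on 6 nodes: a survivor persists iff its partner survives
  A <- matrix(0, 6, 6)
  A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- A[5, 6] <- A[6, 5] <- 1
  dimnames(A) <- list(sprintf("t%02d", 1:6), sprintf("t%02d", 1:6))
  net <- oracle_net_from_adjacency(A)
  r <- robustness(net, remove_frac = 0.5, n_rep = 4000L, seed = 7L)
  # keep 3 of 6 nodes uniformly: P(a kept node's partner also kept) = 2/5
  expect_equal(r, 2 / 5, tolerance = 0.03)
  expect_error(robustness(net, remove_frac = 0), "remove_frac")
})

test_that("cohesion splits into nonnegative and nonpositive parts", {
  set.seed(8)
  X <- matrix(rexp(12 * 10), 12, 10,
              dimnames = list(sprintf("t%02d", 1:12), sprintf("s%02d", 1:10)))
  X <- sweep(X, 2, colSums(X), "/")
  coh <- cohesion(X, n_null = 50L, seed = 1L)
  expect_true(all(coh$cohesion$pos >= 0))
  expect_true(all(coh$cohesion$neg <= 0))
  expect_true(all(coh$connectedness$pos >= 0))
  expect_true(all(coh$connectedness$neg <= 0))
  coh2 <- cohesion(X, n_null = 50L, seed = 1L)
  expect_identical(coh$cohesion, coh2$cohesion)
})

test_that("zi_pi reproduces the textbook roles on a two-clique bridge", {
  A <- matrix(0, 10, 10)
  A[1:5, 1:5] <- 1; A[6:10, 6:10] <- 1
  diag(A) <- 0
  dimnames(A) <- list(sprintf("t%02d", 1:10), sprintf("t%02d", 1:10))
  net <- oracle_net_from_adjacency(A)
  memb <- setNames(rep(1:2, each = 5), rownames(A))
  roles <- zi_pi(net, memb)
  # all within-module degrees equal: zi = 0, pi = 0, peripheral
  expect_equal(roles$zi, rep(0, 10), tolerance = 1e-12)
  expect_equal(roles$pi, rep(0, 10), tolerance = 1e-12)
  expect_true(all(roles$role == "peripheral"))
  expect_error(zi_pi(net, memb[1:5]), "cover")
})

test_that("rmt_threshold rejects dense near-complete regimes", {
  set.seed(9)
  # a correlation matrix that is uniformly strong: every low threshold gives
  # a near-complete graph, which must not be accepted as Poisson
  n <- 40
  f <- rnorm(200)
  X <- vapply(seq_len(n), function(i) 0.95 * f + rnorm(200, 0, 0.3),
              numeric(200))
  r <- cor(X)
  dimnames(r) <- list(sprintf("t%02d", 1:n), sprintf("t%02d", 1:n))
  s <- tryCatch(rmt_threshold(r, s_grid = seq(0.05, 0.99, 0.01)),
                error = function(e) NA_real_)
  if (!is.na(s)) expect_gt(s, 0.5)
})
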