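#' Pearson correlation matrix over taxa
#'
#' Pairwise Pearson correlations (with two-sided p-values) of per-sample
#' relative abundances across the samples of one group. Following standard
#' molecular-ecological-network practice, relative abundances are
#' log-transformed by default (with a pseudocount of half the smallest
#' positive value) so that correlations are computed on the scale where
#' abundance variation is approximately additive; heavy-tailed raw relative
#' abundances otherwise let a few dominant samples drive every coefficient.
#' Taxa with zero variance are excluded with a message.
#'
#' @param table A `pao_otu_table`, or a taxa x samples numeric matrix.
#' @param min_samples Minimum number of samples (default 4).
#' @param transform `"log"` (default) applies `log(x + pseudocount)` to the
#'   relative abundances before correlating; `"none"` uses them as is.
#' @return List of class `corr_matrix`: `r` (taxa x taxa), `p` (same shape),
#'   `n` (samples used), `dropped` (zero-variance taxa).
#' @export
correlation_matrix <- function(table, min_samples = 4L,
                               transform = c("log", "none")) {
  transform <- match.arg(transform)
  X <- if (inherits(table, "pao_otu_table")) relative_abundance(table) else as.matrix(table)
  if (transform == "log") {
    if (any(X < 0, na.rm = TRUE)) {
      stop_invalid("log transform requires non-negative abundances")
    }
    pos <- X[X > 0]
    pseudo <- if (length(pos) > 0) min(pos) / 2 else 1e-12
    X <- log(X + pseudo)
  }
  n <- ncol(X)
  if (n < min_samples) {
    stop_invalid("need at least ", min_samples, " samples, got ", n)
  }
  v <- apply(X, 1, stats::var)
  dropped <- rownames(X)[v == 0 | is.na(v)]
  if (length(dropped) > 0) {
    message("excluding ", length(dropped), " zero-variance taxa")
    X <- X[v > 0 & !is.na(v), , drop = FALSE]
  }
  r <- cor(t(X))
  r[r > 1] <- 1; r[r < -1] <- -1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-15))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(r) <- 1
  diag(p) <- 0
  structure(list(r = r, p = p, n = n, dropped = dropped), class = "corr_matrix")
}

#' Poisson test of the nearest-neighbour spacing distribution
#'
#' Chi-square goodness-of-fit of unfolded nearest-neighbour eigenvalue
#' spacings against the Poisson (exponential) law e^(-s). Eigenvalues are
#' deduplicated (degenerate multiplicities carry no spacing information), the
#' cumulative spectral density is unfolded with a fixed-df smoothing spline,
#' and the spacing histogram is binned at exponential quantiles so every bin
#' has equal expected count (>= 5 after pooling). Spectra with fewer than
#' `min_spacings` distinct spacings are reported as degenerate with p = 1
#' (a fully modular spectrum is the Poisson extreme).
#'
#' @param eigenvalues Numeric eigenvalue vector.
#' @param min_spacings Minimum number of distinct spacings to run the test.
#' @return List `p`, `statistic`, `n_spacings`, `degenerate`.
#' @export
nnsd_poisson_test <- function(eigenvalues, min_spacings = 20L) {
  ev <- sort(eigenvalues)
  ev <- ev[c(TRUE, diff(ev) > 1e-8)]
  m <- length(ev)
  if (m - 1 < min_spacings) {
    return(list(p = 1, statistic = NA_real_, n_spacings = max(m - 1, 0),
                degenerate = TRUE))
  }
  cdf <- seq_len(m) / m
  df_s <- min(8, max(4, floor(m / 10)))
  sp <- smooth.spline(ev, cdf, df = df_s)
  unfolded <- m * predict(sp, ev)$y
  s <- diff(sort(unfolded))
  s <- s[s >= 0]
  s <- s / mean(s)
  k <- max(2L, min(10L, floor(length(s) / 5)))
  breaks <- qexp(seq(0, 1, length.out = k + 1))
  breaks[k + 1] <- Inf
  obs <- table(cut(s, breaks, include.lowest = TRUE))
  expd <- length(s) / k
  stat <- sum((as.numeric(obs) - expd)^2 / expd)
  dfree <- max(1L, k - 2L)   # one df spent normalizing the mean spacing
  list(p = pchisq(stat, dfree, lower.tail = FALSE), statistic = stat,
       n_spacings = length(s), degenerate = FALSE)
}

#' Random matrix theory threshold selection
#'
#' Scans a grid of candidate correlation thresholds; at each, forms the
#' binary adjacency |r| >= s and tests whether the nearest-neighbour spacing
#' distribution (NNSD) of its unfolded eigenvalues follows Poisson
#' statistics. Below the transition the spectrum shows Wigner (GOE) level
#' repulsion; the selected threshold s* is the smallest s whose NNSD accepts
#' Poisson (p > 0.05) and remains accepted at the next grid step. Graphs
#' whose deduplicated spectrum is too small to test (e.g. disjoint cliques or
#' an empty graph) count as accepting — a fully modular spectrum is the
#' Poisson extreme — and are flagged.
#'
#' @param corr A `corr_matrix` (or plain correlation matrix).
#' @param s_grid Candidate thresholds (default 0.30 to 0.99 by 0.01).
#' @param alpha NNSD acceptance level (default 0.05).
#' @return The threshold s* (scalar) with attributes `accepted` (logical per
#'   grid point), `p_values`, and `degenerate` (TRUE when the accepting
#'   spectrum was too degenerate to test, with a warning).
#' @export
rmt_threshold <- function(corr, s_grid = seq(0.30, 0.99, by = 0.01),
                          alpha = 0.05) {
  r <- if (inherits(corr, "corr_matrix")) corr$r else as.matrix(corr)
  if (nrow(r) < 20) {
    stop_invalid("need at least 20 taxa for a meaningful eigenvalue spectrum")
  }
  ar <- abs(r)
  diag(ar) <- 0
  pvals <- numeric(length(s_grid))
  degen <- logical(length(s_grid))
  dense <- logical(length(s_grid))
  for (i in seq_along(s_grid)) {
    A <- (ar >= s_grid[i]) + 0
    # Below the bulk of the correlation distribution the adjacency is
    # near-complete; its collapsed spectrum cannot be unfolded meaningfully
    # and must not count as the Poisson (modular) regime.
    dense[i] <- mean(A[upper.tri(A)]) > 0.5
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    res <- nnsd_poisson_test(ev)
    pvals[i] <- res$p
    degen[i] <- res$degenerate
  }
  accepted <- pvals > alpha & !dense
  run2 <- which(accepted & c(accepted[-1], FALSE))
  if (length(run2) > 0) {
    idx <- run2[1]
    s_star <- s_grid[idx]
    is_degen <- degen[idx]
  } else {
    warning("no threshold accepted Poisson NNSD; returning the grid maximum")
    idx <- length(s_grid)
    s_star <- s_grid[idx]
    is_degen <- TRUE
  }
  if (is_degen && length(run2) > 0) {
    warning("spectrum at the selected threshold is degenerate; ",
            "Poisson accepted by the modular-spectrum convention")
  }
  attr(s_star, "p_values") <- setNames(pvals, s_grid)
  attr(s_star, "accepted") <- accepted
  attr(s_star, "degenerate") <- is_degen
  s_star
}

#' Build a signed co-occurrence network
#'
#' Edges connect taxa with |r| >= s_star and p < `alpha`; the sign of r is
#' recorded and |r| is the edge weight. Isolated nodes are dropped (count
#' reported via message).
#'
#' @param corr A `corr_matrix`.
#' @param s_star Correlation threshold in (0, 1].
#' @param alpha Correlation significance level (default 0.05).
#' @param treatment Optional label stored on the network.
#' @return List of class `co_network`: `graph` (igraph, undirected, edge
#'   attributes `r`, `sign`, `weight` = |r|), `s_star`, `treatment`.
#' @export
build_network <- function(corr, s_star, alpha = 0.05, treatment = NULL) {
  stopifnot(inherits(corr, "corr_matrix"))
  if (s_star <= 0 || s_star > 1) stop_invalid("s_star must be in (0, 1]")
  r <- corr$r
  keep <- abs(r) >= s_star & corr$p < alpha
  diag(keep) <- FALSE
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  if (nrow(idx) == 0) {
    stop_invalid("no edges at s* = ", s_star, " (alpha = ", alpha,
                 "); the threshold removes the entire network")
  }
  edges <- data.frame(
    from = rownames(r)[idx[, 1]],
    to = colnames(r)[idx[, 2]],
    r = r[idx],
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::E(g)$sign <- sign(igraph::E(g)$r)
  igraph::E(g)$weight <- abs(igraph::E(g)$r)
  n_iso <- nrow(r) - igraph::vcount(g)
  if (n_iso > 0) message("dropped ", n_iso, " isolated taxa")
  structure(list(graph = g, s_star = s_star, treatment = treatment),
            class = "co_network")
}

#' Wrap an igraph as a co_network
#'
#' For building networks directly in tests and simulations.
#' @param graph An undirected igraph; missing `r`/`sign` edge attributes are
#'   taken as +1.
#' @param s_star,treatment See [build_network()].
#' @return A `co_network`.
#' @export
as_co_network <- function(graph, s_star = NA_real_, treatment = NULL) {
  if (is.null(igraph::E(graph)$r)) igraph::E(graph)$r <- 1
  if (is.null(igraph::E(graph)$sign)) igraph::E(graph)$sign <- sign(igraph::E(graph)$r)
  structure(list(graph = graph, s_star = s_star, treatment = treatment),
            class = "co_network")
}

#' @export
print.co_network <- function(x, ...) {
  cat("<co_network> ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges (s* = ", format(x$s_star), ")\n", sep = "")
  invisible(x)
}

# Geodesic efficiency: mean over unordered node pairs of 1/d(i,j), with
# 1/Inf = 0 for disconnected pairs.
geodesic_efficiency <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  d <- igraph::distances(g, weights = NA)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

# Stress centrality (Shimbel): number of shortest paths passing through each
# node, normalized by the number of unordered source-target pairs. Brandes-
# style accumulation: path counts sigma forward by BFS level, per-source
# pair dependencies delta backward (delta_s(v) = sigma_s(v) *
# sum_{w in succ(v)} (1 + delta_s(w) / sigma_s(w))).
stress_centrality <- function(g) {
  n <- igraph::vcount(g)
  stress <- numeric(n)
  if (n < 3) return(stress)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  d <- igraph::distances(g, weights = NA)
  for (s in seq_len(n)) {
    ds <- d[s, ]
    reach <- which(is.finite(ds) & seq_len(n) != s)
    if (length(reach) == 0) next
    sigma <- numeric(n)
    sigma[s] <- 1
    for (lev in seq_len(max(ds[reach]))) {
      here <- which(ds == lev)
      prev <- which(ds == lev - 1)
      sigma[here] <- as.numeric(A[here, prev, drop = FALSE] %*% sigma[prev])
    }
    delta <- numeric(n)
    for (lev in rev(seq_len(max(ds[reach]) - 1))) {
      here <- which(ds == lev)
      nxt <- which(ds == lev + 1)
      contrib <- as.numeric(A[here, nxt, drop = FALSE] %*%
                              (1 + delta[nxt] / sigma[nxt]))
      delta[here] <- sigma[here] * contrib
    }
    stress <- stress + delta
  }
  # each unordered pair counted in both directions
  stress / 2 / ((n - 1) * (n - 2) / 2)
}

#' Seeded Louvain partition
#'
#' Louvain community detection with `restarts` seeded runs, keeping the
#' partition with maximal Newman modularity (ties broken by first found).
#'
#' @param net A `co_network` or igraph.
#' @param seed Integer seed.
#' @param restarts Number of restarts (default 10).
#' @return Named integer membership vector.
#' @export
louvain_partition <- function(net, seed = 1L, restarts = 10L) {
  g <- if (inherits(net, "co_network")) net$graph else net
  best <- NULL
  best_q <- -Inf
  for (i in seq_len(restarts)) {
    memb <- with_seed(substream_seed(seed, paste0("louvain", i)), {
      igraph::membership(igraph::cluster_louvain(g, weights = NA))
    })
    q <- igraph::modularity(g, memb)
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- memb
    }
  }
  setNames(as.integer(best), igraph::V(g)$name %||% as.character(seq_along(best)))
}

#' Network complexity metrics
#'
#' The complexity metric panel of the co-occurrence analysis: average local
#' clustering coefficient `C` (nodes of degree < 2 count 0), average degree
#' `k_mean`, degree centralization `C_D`, density `D` and connectance `Conn`
#' (same formula, both reported), edge count `L`, positive edge ratio
#' `L_pos`, efficiency `E` and geodesic efficiency `E_g` (E is an alias of
#' E_g), harmonic geodesic distance `H_g = 1/E_g`, maximal degree `K_max`,
#' maximal eigenvector centrality `E_max` (unit-norm eigenvector), maximal
#' normalized betweenness `B_max`, maximal stress centrality `S_max`,
#' transitivity `T`, and hub count `Hub` (network hubs from [zi_pi()]).
#'
#' @param net A `co_network`.
#' @param partition Optional membership vector for the hub count; computed by
#'   seeded Louvain when NULL.
#' @param seed Seed for the Louvain partition.
#' @return Named list of metric values.
#' @export
complexity_metrics <- function(net, partition = NULL, seed = 1L) {
  g <- net$graph
  n <- igraph::vcount(g)
  if (n < 2) stop_invalid("need at least 2 nodes")
  L <- igraph::ecount(g)
  deg <- igraph::degree(g)
  kmax <- max(deg)
  cd <- if (n > 2) sum(kmax - deg) / ((n - 1) * (n - 2)) else 0
  ltrans <- igraph::transitivity(g, type = "local", isolates = "zero")
  eg <- geodesic_efficiency(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  evec <- eigen(A, symmetric = TRUE)
  v1 <- evec$vectors[, 1]
  v1 <- abs(v1) / sqrt(sum(v1^2))
  bmax <- if (n > 2) {
    max(igraph::betweenness(g, weights = NA)) / ((n - 1) * (n - 2) / 2)
  } else 0
  if (is.null(partition)) partition <- louvain_partition(net, seed = seed)
  roles <- zi_pi(net, partition)
  lpos <- if (L > 0) mean(igraph::E(g)$sign > 0) else NA_real_
  list(
    C = mean(ltrans),
    k_mean = 2 * L / n,
    C_D = cd,
    D = 2 * L / (n * (n - 1)),
    Conn = 2 * L / (n * (n - 1)),
    L = L,
    L_pos = lpos,
    E = eg,
    E_g = eg,
    H_g = if (eg > 0) 1 / eg else Inf,
    K_max = kmax,
    E_max = max(v1),
    B_max = bmax,
    S_max = max(stress_centrality(g)),
    T = igraph::transitivity(g, type = "global"),
    Hub = sum(roles$role == "network hub")
  )
}

# NODF nestedness (0-100) of a binary adjacency, rows/columns sorted by
# degree; standard metric, computed via vegan.
nodf_nestedness <- function(A) {
  A <- (as.matrix(A) > 0) + 0
  if (sum(A) == 0 || all(A == 1)) return(0)
  res <- vegan::nestednodf(A, order = TRUE, weighted = FALSE)
  unname(res$statistic["NODF"])
}

#' Modularity, nestedness, and their null-model relatives
#'
#' `M` is the Newman modularity of the seeded Louvain partition (unweighted),
#' `Com` the number of modules, `N` the NODF nestedness (0-100) of the binary
#' adjacency with rows and columns sorted by degree. Null networks are
#' degree-preserving edge rewirings (10 x L attempted swaps each); relative
#' modularity `RM = (M - mean M_null) / mean M_null` and relative nestedness
#' `RN = (N - mean N_null) / mean N_null`.
#'
#' @param net A `co_network`.
#' @param n_null Number of null rewirings (default 100; < 10 warns).
#' @param seed Seed for Louvain and the rewirings.
#' @return List `M`, `Com`, `N`, `RM`, `RN`, plus `M_null` / `N_null` means.
#' @export
modularity_nestedness <- function(net, n_null = 100L, seed = 1L) {
  g <- net$graph
  if (igraph::ecount(g) < 1) stop_invalid("network has no edges")
  if (n_null < 10) warning("fewer than 10 null networks gives unstable RM/RN")
  memb <- louvain_partition(net, seed = seed)
  M <- igraph::modularity(g, memb)
  Com <- length(unique(memb))
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  N <- nodf_nestedness(A)
  m_null <- numeric(n_null)
  n_null_v <- numeric(n_null)
  for (b in seq_len(n_null)) {
    gb <- with_seed(substream_seed(seed, paste0("rewire", b)), {
      igraph::rewire(g, igraph::keeping_degseq(niter = 10 * igraph::ecount(g)))
    })
    mb <- louvain_partition(as_co_network(gb), seed = substream_seed(seed, paste0("nullq", b)),
                            restarts = 3L)
    m_null[b] <- igraph::modularity(gb, mb)
    n_null_v[b] <- nodf_nestedness(igraph::as_adjacency_matrix(gb, sparse = FALSE))
  }
  mbar <- mean(m_null)
  nbar <- mean(n_null_v)
  list(M = M, Com = Com, N = N,
       RM = if (abs(mbar) > 1e-12) (M - mbar) / mbar else NA_real_,
       RN = if (abs(nbar) > 1e-12) (N - nbar) / nbar else NA_real_,
       M_null_mean = mbar, N_null_mean = nbar)
}

#' Community cohesion
#'
#' Null-corrected, abundance-weighted connectedness: observed pairwise
#' correlations of per-sample relative abundances are corrected by
#' subtracting their expectation under independent within-taxon shuffles;
#' each taxon's positive (negative) connectedness is the mean of its positive
#' (negative) corrected correlations, and per-sample cohesion is the
#' relative-abundance-weighted sum. Cohesion_pos >= 0 >= Cohesion_neg by
#' construction.
#'
#' @param table A `pao_otu_table` or taxa x samples matrix (>= 4 samples).
#' @param n_null Number of shuffle nulls (default 200).
#' @param seed Integer seed.
#' @return List with `cohesion` (data.frame `sample`, `pos`, `neg`) and
#'   `connectedness` (data.frame `taxon`, `pos`, `neg`).
#' @export
cohesion <- function(table, n_null = 200L, seed = 1L) {
  X <- if (inherits(table, "pao_otu_table")) relative_abundance(table) else as.matrix(table)
  if (ncol(X) < 4) stop_invalid("need at least 4 samples")
  v <- apply(X, 1, stats::var)
  X <- X[v > 0, , drop = FALSE]
  M <- t(X)                               # samples x taxa
  r_obs <- cor(M)
  r_null <- matrix(0, ncol(M), ncol(M))
  with_seed(substream_seed(seed, "cohesion"), {
    for (b in seq_len(n_null)) {
      Mp <- apply(M, 2, sample)
      r_null <- r_null + cor(Mp)
    }
  })
  r_null <- r_null / n_null
  corr <- r_obs - r_null
  diag(corr) <- NA
  conn_pos <- apply(corr, 2, function(col) {
    pos <- col[!is.na(col) & col > 0]
    if (length(pos) == 0) 0 else mean(pos)
  })
  conn_neg <- apply(corr, 2, function(col) {
    neg <- col[!is.na(col) & col < 0]
    if (length(neg) == 0) 0 else mean(neg)
  })
  coh_pos <- colSums(X * conn_pos)
  coh_neg <- colSums(X * conn_neg)
  list(
    cohesion = data.frame(sample = colnames(X), pos = unname(coh_pos),
                          neg = unname(coh_neg), stringsAsFactors = FALSE),
    connectedness = data.frame(taxon = rownames(X), pos = unname(conn_pos),
                               neg = unname(conn_neg), stringsAsFactors = FALSE)
  )
}

#' Network robustness to random taxon loss
#'
#' Repeatedly removes a fixed fraction of nodes at random; a surviving node
#' persists when it retains at least one edge among the survivors. Robustness
#' R is the mean fraction of surviving nodes that persist.
#'
#' @param net A `co_network` (>= 4 nodes).
#' @param remove_frac Fraction of nodes removed per repetition, in (0, 1).
#' @param n_rep Repetitions (default 100).
#' @param seed Integer seed.
#' @return Robustness R in \[0, 1\].
#' @export
robustness <- function(net, remove_frac = 0.5, n_rep = 100L, seed = 1L) {
  if (remove_frac <= 0 || remove_frac >= 1) {
    stop_invalid("remove_frac must be in (0, 1)")
  }
  g <- net$graph
  n <- igraph::vcount(g)
  if (n < 4) stop_invalid("need at least 4 nodes")
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  n_remove <- floor(remove_frac * n)
  with_seed(substream_seed(seed, "robustness"), {
    frac <- vapply(seq_len(n_rep), function(b) {
      keep <- sample.int(n, n - n_remove)
      if (length(keep) == 0) return(0)
      sub <- A[keep, keep, drop = FALSE]
      mean(rowSums(sub) > 0)
    }, numeric(1))
    mean(frac)
  })
}

#' Network vulnerability
#'
#' V = max over nodes i of the relative drop in geodesic efficiency when i is
#' deleted, computed on the largest connected component:
#' V = max_i (E_g(G) - E_g(G - i)) / E_g(G).
#'
#' @param net A `co_network` whose largest component has >= 3 nodes.
#' @return Vulnerability V (dimensionless).
#' @export
vulnerability <- function(net) {
  g <- net$graph
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  n <- igraph::vcount(sub)
  if (n < 3) stop_invalid("largest component must have at least 3 nodes")
  e0 <- geodesic_efficiency(sub)
  if (e0 == 0) stop_invalid("geodesic efficiency is zero; V undefined")
  drops <- vapply(seq_len(n), function(i) {
    e0 - geodesic_efficiency(igraph::delete_vertices(sub, i))
  }, numeric(1))
  max(drops) / e0
}

#' Within-module degree (Zi) and participation coefficient (Pi)
#'
#' Zi is the z-score of a node's within-module degree relative to its module
#' (population SD; SD of zero gives Zi = 0). Pi = 1 - sum over modules of
#' (k_im / k_i)^2; isolated nodes get Pi = 0. Roles follow the standard
#' thresholds: network hub (Zi > 2.5 and Pi > 0.62), module hub (Zi > 2.5),
#' connector (Pi > 0.62), else peripheral.
#'
#' @param net A `co_network`.
#' @param partition Named membership vector covering all nodes (e.g. from
#'   [louvain_partition()]).
#' @return data.frame `taxon`, `zi`, `pi`, `role`.
#' @export
zi_pi <- function(net, partition) {
  g <- net$graph
  nodes <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  if (!all(nodes %in% names(partition))) {
    stop_invalid("partition must cover all nodes")
  }
  memb <- partition[nodes]
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  k <- rowSums(A)
  mods <- sort(unique(memb))
  k_in_mod <- vapply(mods, function(m) rowSums(A[, memb == m, drop = FALSE]),
                     numeric(length(nodes)))
  if (length(nodes) == 1) k_in_mod <- matrix(k_in_mod, nrow = 1)
  k_within <- k_in_mod[cbind(seq_along(nodes), match(memb, mods))]
  zi <- numeric(length(nodes))
  for (m in mods) {
    idx <- which(memb == m)
    mu <- mean(k_within[idx])
    sdm <- sqrt(mean((k_within[idx] - mu)^2))
    zi[idx] <- if (sdm > 0) (k_within[idx] - mu) / sdm else 0
  }
  pi <- ifelse(k > 0, 1 - rowSums((k_in_mod / pmax(k, 1))^2), 0)
  role <- ifelse(zi > 2.5 & pi > 0.62, "network hub",
                 ifelse(zi > 2.5, "module hub",
                        ifelse(pi > 0.62, "connector", "peripheral")))
  data.frame(taxon = nodes, zi = zi, pi = pi, role = role,
             stringsAsFactors = FALSE)
}

#' Full metric table for one network
#'
#' Convenience wrapper assembling the complexity panel, modularity and
#' nestedness with null-model relatives, robustness, and vulnerability into
#' one named list.
#'
#' @param net A `co_network`.
#' @param n_null Null count for [modularity_nestedness()].
#' @param n_rep Repetitions for [robustness()].
#' @param seed Integer seed.
#' @return Named list of all metrics.
#' @export
network_metrics <- function(net, n_null = 50L, n_rep = 100L, seed = 1L) {
  part <- louvain_partition(net, seed = seed)
  cm <- complexity_metrics(net, partition = part, seed = seed)
  mn <- modularity_nestedness(net, n_null = n_null, seed = seed)
  V <- tryCatch(vulnerability(net), error = function(e) NA_real_)
  c(cm, mn[c("M", "Com", "N", "RM", "RN")],
    list(R = robustness(net, n_rep = n_rep, seed = seed), V = V))
}

#' Write a network edge list as TSV
#'
#' @param net A `co_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edgelist_tsv <- function(net, path) {
  el <- igraph::as_data_frame(net$graph, what = "edges")
  el <- el[, c("from", "to", "r", "sign")]
  write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
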