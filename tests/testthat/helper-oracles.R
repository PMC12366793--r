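# Brute-force reference implementations of the graph metric panel, written
# directly from the definitions (adjacency-matrix loops, exhaustive path
# enumeration) with no igraph calls, for cross-checking the package metrics
# on small graphs.

# Random connected undirected graph on n nodes as a 0/1 adjacency matrix:
# Erdos-Renyi edges on top of a random spanning tree.
oracle_random_graph <- function(n, p = 0.4) {
  A <- matrix(0L, n, n)
  perm <- sample.int(n)
  for (i in seq_len(n - 1)) {         # random spanning tree: connectivity
    a <- perm[i + 1]
    b <- perm[sample.int(i, 1)]
    A[a, b] <- A[b, a] <- 1L
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (A[i, j] == 0 && runif(1) < p) A[i, j] <- A[j, i] <- 1L
  }
  dimnames(A) <- list(sprintf("t%02d", seq_len(n)), sprintf("t%02d", seq_len(n)))
  A
}

oracle_net_from_adjacency <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  as_co_network(g)
}

# All-pairs shortest path lengths by Floyd-Warshall.
oracle_distances <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[A > 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# Exhaustive enumeration of all shortest paths between s and t (as vectors of
# interior nodes), by depth-first search over simple paths.
oracle_shortest_paths <- function(A, s, t) {
  n <- nrow(A)
  d <- oracle_distances(A)
  if (!is.finite(d[s, t])) return(list())
  paths <- list()
  walk <- function(v, trail) {
    if (v == t) {
      if (length(trail) - 1 == d[s, t]) paths[[length(paths) + 1]] <<- trail
      return()
    }
    if (length(trail) - 1 >= d[s, t]) return()
    for (w in which(A[v, ] > 0)) {
      if (!(w %in% trail)) walk(w, c(trail, w))
    }
  }
  walk(s, s)
  paths
}

oracle_local_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(A[nb, nb]) / 2
    links / (k * (k - 1) / 2)
  }, numeric(1))
}

oracle_transitivity <- function(A) {
  n <- nrow(A)
  triangles <- 0
  triples <- 0
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    triples <- triples + k * (k - 1) / 2
    if (k >= 2) triangles <- triangles + sum(A[nb, nb]) / 2
  }
  if (triples == 0) return(NaN)
  triangles / triples
}

oracle_geodesic_efficiency <- function(A) {
  d <- oracle_distances(A)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- oracle_shortest_paths(A, s, t)
    if (length(paths) == 0) next
    for (pth in paths) {
      interior <- setdiff(pth, c(s, t))
      btw[interior] <- btw[interior] + 1 / length(paths)
    }
  }
  btw
}

oracle_stress <- function(A) {
  n <- nrow(A)
  st <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- oracle_shortest_paths(A, s, t)
    for (pth in paths) {
      interior <- setdiff(pth, c(s, t))
      st[interior] <- st[interior] + 1
    }
  }
  st / ((n - 1) * (n - 2) / 2)
}

oracle_degree_centralization <- function(A) {
  k <- rowSums(A)
  n <- nrow(A)
  if (n <= 2) return(0)
  sum(max(k) - k) / ((n - 1) * (n - 2))
}

# Newman modularity of a fixed partition, from the definitional double sum.
oracle_modularity <- function(A, memb) {
  k <- rowSums(A)
  m2 <- sum(k)
  if (m2 == 0) return(NaN)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (memb[i] == memb[j]) q <- q + A[i, j] - k[i] * k[j] / m2
  }
  as.numeric(q / m2)
}

# NODF (Almeida-Neto et al.) of a binary matrix with rows and columns sorted
# by decreasing degree: paired overlap is zero unless the first line has
# strictly larger degree, else 100 x the fraction of the sparser line's
# presences shared.
oracle_nodf <- function(A) {
  A <- (as.matrix(A) > 0) + 0
  A <- A[order(-rowSums(A)), order(-colSums(A)), drop = FALSE]
  pair_sum <- function(M) {
    deg <- rowSums(M)
    total <- 0
    nr <- nrow(M)
    for (i in seq_len(nr - 1)) for (j in (i + 1):nr) {
      if (deg[j] == 0 || deg[i] <= deg[j]) next
      total <- total + 100 * sum(M[i, ] * M[j, ]) / deg[j]
    }
    total
  }
  nr <- nrow(A); nc <- ncol(A)
  denom <- nr * (nr - 1) / 2 + nc * (nc - 1) / 2
  as.numeric((pair_sum(A) + pair_sum(t(A))) / denom)
}

# Within-module degree z-score and participation coefficient, direct loops.
oracle_zipi <- function(A, memb) {
  n <- nrow(A)
  k <- rowSums(A)
  mods <- sort(unique(memb))
  k_within <- vapply(seq_len(n), function(i) sum(A[i, memb == memb[i]]), numeric(1))
  zi <- numeric(n)
  for (m in mods) {
    idx <- which(memb == m)
    mu <- mean(k_within[idx])
    sdm <- sqrt(mean((k_within[idx] - mu)^2))
    zi[idx] <- if (sdm > 0) (k_within[idx] - mu) / sdm else 0
  }
  pi <- vapply(seq_len(n), function(i) {
    if (k[i] == 0) return(0)
    1 - sum(vapply(mods, function(m) (sum(A[i, memb == m]) / k[i])^2, numeric(1)))
  }, numeric(1))
  list(zi = zi, pi = pi)
}

# Adjusted Rand index between two labelings.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  ex <- sa * sb / choose(n, 2)
  (si - ex) / ((sa + sb) / 2 - ex)
}
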