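# Independent brute-force graph oracles, deliberately implemented without
# igraph (matrix Floyd-Warshall, exhaustive geodesic counting, A^3 triangle
# counts) so they can cross-check the package implementations.

fw_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], "+")
    d <- pmin(d, dk)
  }
  d
}

brute_efficiency <- function(d) {
  inv <- 1 / d
  diag(inv) <- 0
  n <- nrow(d)
  sum(inv) / (n * (n - 1))
}

brute_clustering <- function(a) {
  k <- rowSums(a)
  tri <- diag(a %*% a %*% a) / 2
  ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
}

brute_eloc <- function(a) {
  n <- nrow(a)
  mean(sapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2) return(0)
    brute_efficiency(fw_distances(a[nb, nb, drop = FALSE]))
  }))
}

# geodesic-counting betweenness from first principles: sigma[s,t] by
# dynamic programming over distance shells, then pair contributions
brute_betweenness <- function(a) {
  n <- nrow(a)
  d <- fw_distances(a)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    reach <- which(is.finite(d[s, ]))
    for (t in reach[order(d[s, reach])]) {
      if (t == s) next
      pred <- which(a[, t] > 0 & d[s, ] == d[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, pred])
    }
  }
  b <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s >= t || s == v || t == v) next
        if (!is.finite(d[s, t]) || sigma[s, t] == 0) next
        if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t]) {
          b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  b
}

rand_adjacency <- function(n, p) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}

path_graph <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
  a
}

complete_graph <- function(n) {
  a <- matrix(1, n, n)
  diag(a) <- 0
  a
}

star_graph <- function(n) {
  a <- matrix(0, n, n)
  a[1, 2:n] <- a[2:n, 1] <- 1
  a
}

ring_lattice <- function(n, k) {
  a <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(k / 2)) {
    nb <- ((i - 1 + j) %% n) + 1
    a[i, nb] <- a[nb, i] <- 1
  }
  a
}

er_adjacency <- function(n, p, seed) {
  set.seed(seed)
  rand_adjacency(n, p)
}
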