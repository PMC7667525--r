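# Shared fixtures, built in code and memoised per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

fixture_geom <- function(n = 60, seed = 11) {
  memo(sprintf("geom_%d_%d", n, seed),
       function() generate_geometry(1, n, seed = seed)[[1]])
}

fixture_graph <- function(n = 60, seed = 11, k = 10) {
  memo(sprintf("graph_%d_%d_%d", n, seed, k),
       function() build_knn_graph(fixture_geom(n, seed)$dist, k = k))
}

# A hand-specified path graph: node i adjacent to i-1 and i+1.
path_graph <- function(n) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) w[i, i + 1] <- w[i + 1, i] <- 1
  spatial_graph(w)
}

# Brute-force Moran's I from the definition (double sum over all pairs).
moran_brute <- function(x, w) {
  n <- length(x)
  z <- x - mean(x)
  s0 <- sum(w)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) num <- num + w[i, j] * z[i] * z[j]
  }
  (n / s0) * num / sum(z^2)
}

# Classical Spearman test via the t approximation (the oracle the
# rank-regression route must reproduce exactly in the tie-free case).
spearman_oracle <- function(x, y) {
  n <- length(x)
  rho <- cor(x, y, method = "spearman")
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, t = t, p = 2 * pt(abs(t), n - 2, lower.tail = FALSE))
}

# One-sided hypergeometric upper tail from first principles (choose() sums).
hyper_tail_oracle <- function(a, n_set, n_list, n_bg) {
  j <- a:min(n_set, n_list)
  sum(choose(n_set, j) * choose(n_bg - n_set, n_list - j)) /
    choose(n_bg, n_list)
}
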