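#' Moran's I test for spatial autocorrelation
#'
#' Computes Moran's I over a spatial weights graph,
#' `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`,
#' with expectation `-1/(n-1)` and variance under the randomisation
#' (permutation-moment) assumption, which conditions on the observed values
#' and uses their sample kurtosis. The default alternative is "greater":
#' positive autocorrelation is the alarmed direction when the test screens
#' regression residuals.
#'
#' @param x Numeric vector with positive variance, one value per node.
#' @param g A [build_knn_graph()] / [spatial_graph()] object.
#' @param alternative One of "greater", "less", "two.sided".
#' @return A `moran_test` object with fields `I`, `expected`, `variance`,
#'   `z`, `p`, `alternative`, `n`.
#' @examples
#' geom <- generate_geometry(1, 50, seed = 2)[[1]]
#' g <- build_knn_graph(geom$dist, k = 10)
#' moran_I(geom$coords[, 1], g)  # a coordinate is maximally smooth
#' @export
moran_I <- function(x, g, alternative = c("greater", "less", "two.sided")) {
  stopifnot(inherits(g, "spatial_graph"))
  alternative <- match.arg(alternative)
  n <- g$n
  if (length(x) != n) abort("`x` must have one value per node.")
  z <- x - mean(x)
  m2 <- sum(z^2)
  if (m2 == 0) abort("`x` is constant; Moran's I is undefined.")
  obs <- moran_stat(z, g)
  expected <- -1 / (n - 1)
  s0 <- g$s0; s1 <- g$s1; s2 <- g$s2
  b2 <- n * sum(z^4) / m2^2
  v <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
          b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * s0^2) - expected^2
  zscore <- (obs - expected) / sqrt(v)
  p <- switch(alternative,
    greater = pnorm(zscore, lower.tail = FALSE),
    less = pnorm(zscore),
    two.sided = 2 * pnorm(abs(zscore), lower.tail = FALSE)
  )
  structure(
    list(I = obs, expected = expected, variance = v, z = zscore, p = p,
         alternative = alternative, n = n),
    class = "moran_test"
  )
}

# Statistic only, on an already-centered vector; hot path of the
# eigenvector-escalation loop.
moran_stat <- function(z, g) {
  (g$n / g$s0) * sum(z * as.numeric(g$weights %*% z)) / sum(z^2)
}

#' @export
print.moran_test <- function(x, ...) {
  cat(sprintf(
    "Moran's I = %.4f (expected %.4f), z = %.3f, p = %.4g [%s], n = %d\n",
    x$I, x$expected, x$z, x$p, x$alternative, x$n
  ))
  invisible(x)
}

#' @rdname moran_I
#' @param x A `moran_test` object (for `tidy`).
#' @param ... Unused.
#' @export
tidy.moran_test <- function(x, ...) {
  tibble::tibble(
    estimate = x$I, expected = x$expected, variance = x$variance,
    statistic = x$z, p.value = x$p, alternative = x$alternative, n = x$n
  )
}
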