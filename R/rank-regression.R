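#' Rank-transform a vector
#'
#' Ranks 1..n with ties replaced by their average rank — the transform under
#' which ordinary least squares reproduces the Spearman rank correlation.
#'
#' @param x Numeric vector.
#' @return Numeric vector of (average-tie) ranks.
#' @examples
#' rank_transform(c(5, 5, 9))  # 1.5 1.5 3
#' @export
rank_transform <- function(x) rank(x, ties.method = "average")

#' Spatially adjusted rank regression of atrophy on expression
#'
#' Approximates the Spearman correlation between atrophy t-scores and a
#' probe's expression while absorbing spatial autocorrelation: both variables
#' are rank-transformed and the atrophy ranks are regressed on the expression
#' ranks. If the residuals show spatial autocorrelation (Moran test p below
#' `alpha`), Moran eigenvectors are added as confound covariates — first a
#' single eigenvector, then in batches of five (m = 0, 1, 5, 10, ...) — until
#' the residuals are clean or the cap is reached. The expression
#' coefficient's t-statistic and two-sided p-value from the final model are
#' reported; with zero eigenvectors these equal the classical Spearman test.
#'
#' @param t_vals Atrophy t-scores, one per sample (the response, as ranks).
#' @param expr Expression values, one per sample (the predictor, as ranks).
#' @param basis An [compute_mem()] basis, or `NULL` to skip spatial
#'   adjustment entirely (plain rank regression).
#' @param graph The [build_knn_graph()] graph used for the residual Moran
#'   test; required when `basis` is given.
#' @param alpha Residual Moran test level that triggers escalation.
#' @param cap Maximum number of eigenvectors considered.
#' @param schedule Optional increasing integer vector of eigenvector counts
#'   to try; default `c(0, 1, 5, 10, ..., cap)`, truncated so the model keeps
#'   at least two residual degrees of freedom.
#' @return An `sevm_fit` with the slope `estimate` (equal to Spearman's rho
#'   when no eigenvectors enter and there are no ties), `statistic` (t),
#'   `p.value` (two-sided), `n_eigenvectors`, `residual_moran_p`, `n`, `df`.
#' @examples
#' geom <- generate_geometry(1, 60, seed = 3)[[1]]
#' g <- build_knn_graph(geom$dist, k = 10)
#' fit_with_sevm(rnorm(60), rnorm(60), compute_mem(g), g)
#' @export
fit_with_sevm <- function(t_vals, expr, basis = NULL, graph = NULL,
                          alpha = 0.05, cap = 150, schedule = NULL) {
  if (length(t_vals) != length(expr)) {
    abort("`t_vals` and `expr` must have the same length.")
  }
  if (!is.null(basis) && is.null(graph)) {
    abort("`graph` is required for the residual Moran test when `basis` is given.")
  }
  if (var(expr) == 0) abort("`expr` is constant; rank regression is undefined.")
  fit_sevm_ranks(rank_transform(t_vals), rank_transform(expr),
                 basis, graph, alpha, cap, schedule)
}

# Core escalation loop on pre-computed ranks (reused across probes, where the
# response ranks are shared).
fit_sevm_ranks <- function(ry, rx, basis, graph, alpha = 0.05, cap = 150,
                           schedule = NULL) {
  n <- length(ry)
  if (is.null(schedule)) {
    schedule <- if (is.null(basis)) 0L else c(0L, 1L, seq(5L, cap, by = 5L))
  }
  schedule <- schedule[schedule <= min(cap, n - 3, if (is.null(basis)) 0 else
    ncol(basis$vectors))]
  if (length(schedule) == 0) schedule <- 0L
  last <- schedule[length(schedule)]
  moran_p <- NA_real_
  for (m in schedule) {
    x <- cbind(1, rx, if (m > 0) basis$vectors[, seq_len(m), drop = FALSE])
    qx <- qr(x)
    if (qx$rank < ncol(x)) {
      abort(sprintf("design matrix rank-deficient with m = %d eigenvectors.", m))
    }
    res <- qr.resid(qx, ry)
    if (is.null(basis)) break
    rss <- sum(res^2)
    if (rss < 1e-12 * sum((ry - mean(ry))^2)) {
      moran_p <- 1  # perfect fit leaves nothing spatial to test
      break
    }
    moran_p <- moran_I(res, graph, alternative = "greater")$p
    if (moran_p >= alpha || m == last) break
  }
  p_cols <- ncol(x)
  df <- n - p_cols
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  pos <- which(qx$pivot == 2L)
  beta <- qr.coef(qx, ry)[2L]
  se <- sqrt(sigma2 * xtx_inv[pos, pos])
  tstat <- beta / se
  structure(
    list(
      estimate = unname(beta), statistic = unname(tstat),
      p.value = 2 * pt(abs(tstat), df, lower.tail = FALSE),
      n_eigenvectors = as.integer(m), residual_moran_p = moran_p, n = n,
      df = df
    ),
    class = "sevm_fit"
  )
}

#' @export
print.sevm_fit <- function(x, ...) {
  cat(sprintf(
    "<sevm_fit> slope %.4f, t = %.3f, p = %.4g | %d eigenvector(s), residual Moran p = %.3g\n",
    x$estimate, x$statistic, x$p.value, x$n_eigenvectors, x$residual_moran_p
  ))
  invisible(x)
}

#' @rdname fit_with_sevm
#' @param x,object An `sevm_fit`.
#' @param ... Unused.
#' @export
tidy.sevm_fit <- function(x, ...) {
  tibble::tibble(
    term = "expression", estimate = x$estimate, statistic = x$statistic,
    p.value = x$p.value
  )
}

#' @rdname fit_with_sevm
#' @export
glance.sevm_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, df.residual = x$df, n_eigenvectors = x$n_eigenvectors,
    residual_moran_p = x$residual_moran_p
  )
}
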