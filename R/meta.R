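#' Combine per-donor tests with sign-weighted Stouffer's method
#'
#' Each donor's two-sided p-value is converted to a nonnegative normal
#' quantile `Z_i = qnorm(1 - p_i/2)` and weighted by the sign of its
#' regression t-statistic; weights are restricted to -1/+1 so that donors
#' with more samples do not dominate:
#' `z_meta = sum(w_i Z_i) / sqrt(sum(w_i^2))`, `p_meta = 2 (1 - pnorm(|z_meta|))`.
#' P-values are clamped to `[1e-300, 1 - 1e-16]` before inversion.
#'
#' @param per_donor Data frame with one row per donor and columns `p`
#'   (two-sided p-value) and `statistic` (signed t); at least two donors.
#' @return One-row tibble with `z_meta`, `p_meta`, `n_donors`, `direction`.
#' @examples
#' d <- tibble::tibble(p = rep(2 * pnorm(-2), 6), statistic = rep(1, 6))
#' stouffer_combine(d)  # z_meta = 12/sqrt(6)
#' @export
stouffer_combine <- function(per_donor) {
  if (!all(c("p", "statistic") %in% names(per_donor))) {
    abort("`per_donor` needs columns `p` and `statistic`.")
  }
  z <- stouffer_z(per_donor$p, sign(per_donor$statistic))
  tibble::tibble(
    z_meta = z,
    p_meta = 2 * pnorm(abs(z), lower.tail = FALSE),
    n_donors = nrow(per_donor),
    direction = sign(z)
  )
}

# Vector core shared with the pipeline's grouped summarise.
stouffer_z <- function(p, w) {
  if (length(p) < 2) abort("Stouffer combination needs at least 2 donors.")
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  zi <- qnorm(p / 2, lower.tail = FALSE)
  sum(w * zi) / sqrt(sum(w^2))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR q-values: `q_(i) = min_{j >= i} (m * p_(j) / j)`, capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}
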