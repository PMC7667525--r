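# Shared internal helpers.

# round() in R rounds half to even; voxel lookup wants half away from zero so
# that e.g. index 2.5 maps to voxel 3 regardless of parity.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Validate a distance matrix: square, symmetric, zero diagonal, nonnegative.
check_dist_matrix <- function(d, arg = "dist") {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    abort(sprintf("`%s` must be a square matrix.", arg))
  }
  if (any(d < 0)) abort(sprintf("`%s` has negative entries.", arg))
  if (any(abs(diag(d)) > 1e-12)) {
    abort(sprintf("`%s` must have a zero diagonal.", arg))
  }
  if (max(abs(d - t(d))) > 1e-8 * max(1, max(abs(d)))) {
    abort(sprintf("`%s` must be symmetric.", arg))
  }
  invisible(d)
}

check_count <- function(x, arg, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", arg, min))
  }
  as.integer(x)
}

# Zero-padded identifier vectors used by the generators.
make_ids <- function(prefix, n) {
  sprintf(paste0(prefix, "%0", max(4, nchar(n)), "d"), seq_len(n))
}
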