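#' Build a k-nearest-neighbour spatial weights graph
#'
#' Nodes i and j are adjacent iff j is among i's k nearest neighbours or
#' vice versa (union symmetrisation). Ties at the k-th distance are broken by
#' smallest index. The binary adjacency is row-standardised into spatial
#' weights, the convention of standard spatial-statistics tooling: every row
#' with at least one neighbour sums to one (union symmetrisation guarantees
#' at least k neighbours per node). Moments of the weight matrix used by the
#' Moran test are precomputed and cached on the object.
#'
#' @param dist Symmetric distance matrix with zero diagonal (mm), e.g. the
#'   `dist` of a [donor_geometry()].
#' @param k Number of nearest neighbours.
#' @return A `spatial_graph` with fields `n`, `k`, `adjacency` (sparse
#'   binary), `weights` (sparse row-standardised) and cached `s0`, `s1`, `s2`.
#' @examples
#' geom <- generate_geometry(1, 40, seed = 1)[[1]]
#' g <- build_knn_graph(geom$dist, k = 10)
#' @export
build_knn_graph <- function(dist, k = 10) {
  dist <- as.matrix(dist)
  check_dist_matrix(dist)
  k <- check_count(k, "k")
  n <- nrow(dist)
  if (n <= k) abort(sprintf("need more than k = %d points, got %d.", k, n))
  adj <- knn_adjacency(dist, k)
  w <- Matrix::Matrix(adj / rowSums(adj), sparse = TRUE)
  wt <- Matrix::t(w)
  rs <- Matrix::rowSums(w)
  cs <- Matrix::colSums(w)
  structure(
    list(
      n = n, k = k,
      adjacency = Matrix::Matrix(adj, sparse = TRUE),
      weights = w,
      s0 = sum(rs),
      s1 = 0.5 * sum((w + wt)^2),
      s2 = sum((rs + cs)^2)
    ),
    class = "spatial_graph"
  )
}

#' Wrap an arbitrary spatial weight matrix as a graph
#'
#' For non-k-NN weight structures (e.g. hand-built test graphs). The matrix
#' is row-standardised unless already so.
#'
#' @param w Nonnegative square weight matrix with zero diagonal.
#' @param row_standardise Divide each nonzero row by its sum.
#' @return A `spatial_graph`.
#' @export
spatial_graph <- function(w, row_standardise = TRUE) {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w)) abort("`w` must be square.")
  if (any(w < 0)) abort("`w` must be nonnegative.")
  if (any(diag(w) != 0)) abort("`w` must have a zero diagonal.")
  adj <- (w > 0) * 1L
  if (row_standardise) {
    rs <- rowSums(w)
    w <- w / ifelse(rs > 0, rs, 1)
  }
  w <- Matrix::Matrix(w, sparse = TRUE)
  rs <- Matrix::rowSums(w)
  cs <- Matrix::colSums(w)
  structure(
    list(
      n = nrow(w), k = NA_integer_,
      adjacency = Matrix::Matrix(adj, sparse = TRUE),
      weights = w,
      s0 = sum(rs),
      s1 = 0.5 * sum((w + Matrix::t(w))^2),
      s2 = sum((rs + cs)^2)
    ),
    class = "spatial_graph"
  )
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("<spatial_graph> %d nodes, %d edges (k = %s)\n",
              x$n, sum(x$adjacency) / 2,
              ifelse(is.na(x$k), "custom", x$k)))
  invisible(x)
}
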