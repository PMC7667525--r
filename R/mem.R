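#' Moran eigenvector maps of a spatial graph
#'
#' Eigendecomposition of the doubly centered, symmetrised weight matrix
#' `C %*% (W + t(W))/2 %*% C` with `C = I - 11'/n`. The eigenvectors are
#' mutually orthogonal spatial patterns ordered by eigenvalue (descending),
#' so patterns of strongest positive spatial autocorrelation come first: the
#' leading eigenvector attains the maximal Moran's I achievable by any
#' centered vector on that graph. Eigenvectors whose |eigenvalue| falls below
#' 1e-12 of the largest are dropped (this removes the constant pattern).
#'
#' @param g A [build_knn_graph()] / [spatial_graph()] object with at least 3
#'   nodes.
#' @return An `mem_basis` with `vectors` (n x m, unit columns) and `values`
#'   (m, descending).
#' @examples
#' geom <- generate_geometry(1, 40, seed = 1)[[1]]
#' basis <- compute_mem(build_knn_graph(geom$dist, k = 10))
#' @export
compute_mem <- function(g) {
  stopifnot(inherits(g, "spatial_graph"))
  n <- g$n
  if (n < 3) abort("need at least 3 nodes for an eigenvector basis.")
  w <- as.matrix((g$weights + Matrix::t(g$weights)) / 2)
  # double centering: subtract row means, column means, add grand mean
  rm_ <- rowMeans(w); cm_ <- colMeans(w); gm <- mean(w)
  m <- w - outer(rm_, rep(1, n)) - outer(rep(1, n), cm_) + gm
  eig <- eigen((m + t(m)) / 2, symmetric = TRUE)
  keep <- abs(eig$values) > 1e-12 * max(abs(eig$values))
  structure(
    list(vectors = eig$vectors[, keep, drop = FALSE],
         values = eig$values[keep]),
    class = "mem_basis"
  )
}

#' @export
print.mem_basis <- function(x, ...) {
  cat(sprintf(
    "<mem_basis> %d eigenvectors (n = %d), eigenvalues %.3f .. %.3f\n",
    ncol(x$vectors), nrow(x$vectors), x$values[1],
    x$values[length(x$values)]
  ))
  invisible(x)
}
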