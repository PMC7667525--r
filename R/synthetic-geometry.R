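#' Generate synthetic donor sample geometries
#'
#' Emulates the geometry of cortical microarray sampling: for each donor,
#' samples are scattered over a curved two-dimensional sheet embedded in 3-D
#' world (MNI-like, mm) space, and pairwise distances are measured along the
#' sheet rather than through it. Distances are shortest-path lengths over a
#' dense Euclidean neighbour mesh on the sampled points, a standard discrete
#' surrogate for surface geodesics.
#'
#' @param n_donors Number of donors to simulate.
#' @param n_samples Samples per donor (at least 20; the downstream 10-NN
#'   graph needs headroom).
#' @param seed Integer seed; the output is a pure function of the arguments.
#' @param extent_mm Side length of the sheet's parameter square, mm. The
#'   default 80 mm gives a median nearest-neighbour spacing of roughly 3 mm
#'   at 200 samples, comparable to cortical microarray sampling density.
#' @param fold_amp_mm,fold_wavelength_mm Amplitude and wavelength of the
#'   sheet's out-of-plane folding, mm.
#'
#' @return A list of `donor_geometry` objects, each with `donor_id`,
#'   `coords` (n x 3 matrix, mm) and `dist` (n x n symmetric geodesic
#'   surrogate matrix, mm).
#' @examples
#' geoms <- generate_geometry(2, 40, seed = 1)
#' geoms[[1]]
#' @export
generate_geometry <- function(n_donors, n_samples, seed,
                              extent_mm = 80, fold_amp_mm = 15,
                              fold_wavelength_mm = 20) {
  n_donors <- check_count(n_donors, "n_donors")
  n_samples <- check_count(n_samples, "n_samples")
  if (n_samples < 20) {
    abort("`n_samples` must be at least 20 for a usable neighbour mesh.")
  }
  withr::with_seed(seed, {
    purrr::map(seq_len(n_donors), function(d) {
      phase <- runif(2, 0, 2 * pi)
      u <- runif(n_samples, 0, extent_mm)
      v <- runif(n_samples, 0, extent_mm)
      z <- fold_amp_mm *
        sin(u / fold_wavelength_mm + phase[1]) *
        cos(v / fold_wavelength_mm + phase[2])
      # left-hemisphere-like offset so world coordinates look MNI-ish
      coords <- cbind(x = -u - 5, y = v - 40, z = z)
      rownames(coords) <- make_ids(sprintf("D%d_S", d), n_samples)
      new_donor_geometry(paste0("donor", d), coords,
                         mesh_geodesic_dist(coords))
    })
  })
}

new_donor_geometry <- function(donor_id, coords, dist) {
  structure(
    list(donor_id = donor_id, coords = coords, dist = dist),
    class = "donor_geometry"
  )
}

#' Construct a donor geometry from externally supplied data
#'
#' Accepts any coordinate set and (optionally) any externally computed
#' distance matrix — e.g. true surface geodesics — so real data can stand in
#' for the synthetic sheet. When `dist` is omitted it is rebuilt as the
#' mesh-geodesic surrogate.
#'
#' @param donor_id Donor identifier.
#' @param coords n x 3 numeric matrix of world coordinates, mm.
#' @param dist Optional n x n symmetric distance matrix, mm.
#' @return A `donor_geometry` object.
#' @export
donor_geometry <- function(donor_id, coords, dist = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) abort("`coords` must have three columns.")
  if (is.null(rownames(coords))) {
    rownames(coords) <- make_ids(paste0(donor_id, "_S"), nrow(coords))
  }
  if (is.null(dist)) {
    dist <- mesh_geodesic_dist(coords)
  } else {
    dist <- as.matrix(dist)
    check_dist_matrix(dist)
    if (nrow(dist) != nrow(coords)) {
      abort("`dist` must match `coords` in size.")
    }
  }
  new_donor_geometry(donor_id, coords, dist)
}

# Shortest-path distances over a symmetrised k-NN mesh with Euclidean edge
# weights; k grows until the mesh is connected.
mesh_geodesic_dist <- function(coords, k_mesh = 8) {
  n <- nrow(coords)
  euclid <- as.matrix(stats::dist(coords))
  repeat {
    adj <- knn_adjacency(euclid, min(k_mesh, n - 1))
    g <- igraph::graph_from_adjacency_matrix(
      adj * euclid, mode = "undirected", weighted = TRUE
    )
    if (igraph::is_connected(g)) break
    k_mesh <- k_mesh + 4
  }
  d <- igraph::distances(g)
  dimnames(d) <- list(rownames(coords), rownames(coords))
  d
}

# Binary union-symmetrised k-NN adjacency from a dense distance matrix.
# Ties at the k-th distance are broken by smallest index (order() default).
knn_adjacency <- function(d, k) {
  n <- nrow(d)
  adj <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, -i])[seq_len(k)]
    nb <- seq_len(n)[-i][nb]
    adj[i, nb] <- 1L
  }
  pmax(adj, t(adj))
}

#' @export
print.donor_geometry <- function(x, ...) {
  cat(sprintf(
    "<donor_geometry> %s: %d samples, geodesic distances up to %.1f mm\n",
    x$donor_id, nrow(x$coords), max(x$dist)
  ))
  invisible(x)
}
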