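#' Construct an atrophy t-statistic volume
#'
#' @param grid 3-D numeric array of voxel-wise t-statistics.
#' @param affine 4 x 4 matrix mapping homogeneous 0-based voxel indices to
#'   world coordinates (mm); must be invertible.
#' @param map_id Label for the map (e.g. the genetic group it contrasts).
#' @return An `atrophy_volume`.
#' @export
atrophy_volume <- function(grid, affine, map_id = "map") {
  if (length(dim(grid)) != 3) abort("`grid` must be a 3-D array.")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L))) abort("`affine` must be 4 x 4.")
  if (abs(det(affine)) < 1e-12) abort("`affine` is singular.")
  structure(list(grid = grid, affine = affine, map_id = map_id),
            class = "atrophy_volume")
}

#' Generate a smooth synthetic atrophy volume
#'
#' Emulates a voxel-based-morphometry t-map as a radial Gaussian bump in
#' world space: `t(v) = peak_t * exp(-||world(v) - focus_center||^2 /
#' (2 * focus_scale^2))`, so atrophy is maximal at `focus_center` and decays
#' smoothly — the spatial smoothness that makes naive correlation against
#' equally smooth expression anti-conservative.
#'
#' @param grid_shape Integer vector of three positive voxel counts.
#' @param affine 4 x 4 voxel-to-world matrix (0-based indices), invertible.
#' @param focus_center World coordinate (mm) of peak atrophy.
#' @param focus_scale Gaussian radius, mm.
#' @param peak_t Peak t-statistic.
#' @param map_id Label for the map.
#' @return An `atrophy_volume`.
#' @examples
#' aff <- diag(4); aff[1:3, 4] <- c(-50, -50, -30)
#' vol <- generate_atrophy_volume(c(40, 40, 30), aff,
#'                                focus_center = c(-30, -20, -10),
#'                                focus_scale = 15, peak_t = 6)
#' @export
generate_atrophy_volume <- function(grid_shape, affine, focus_center,
                                    focus_scale, peak_t, map_id = "map") {
  grid_shape <- vapply(grid_shape, check_count, integer(1), arg = "grid_shape")
  if (length(grid_shape) != 3) abort("`grid_shape` must have three entries.")
  affine <- as.matrix(affine)
  if (abs(det(affine)) < 1e-12) abort("`affine` is singular.")
  idx <- as.matrix(expand.grid(
    i = seq_len(grid_shape[1]) - 1,
    j = seq_len(grid_shape[2]) - 1,
    k = seq_len(grid_shape[3]) - 1
  ))
  world <- t(affine %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
  d2 <- rowSums(sweep(world, 2, focus_center)^2)
  grid <- array(peak_t * exp(-d2 / (2 * focus_scale^2)), dim = grid_shape)
  atrophy_volume(grid, affine, map_id)
}

#' @export
print.atrophy_volume <- function(x, ...) {
  cat(sprintf("<atrophy_volume> %s: %s grid, t in [%.2f, %.2f]\n",
              x$map_id, paste(dim(x$grid), collapse = "x"),
              min(x$grid), max(x$grid)))
  invisible(x)
}
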