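#' Sample a statistical volume at world coordinates
#'
#' Nearest-voxel lookup: each world coordinate is mapped through the inverse
#' affine, each axis index is rounded half away from zero, and the value of
#' that voxel is returned. No interpolation is performed — the t-score
#' reported is the one of the voxel containing (or nearest to) the
#' coordinate.
#'
#' @param coords World coordinates, mm: an n x 3 matrix, or a data frame with
#'   `mni_x`, `mni_y`, `mni_z` columns.
#' @param vol An [atrophy_volume()].
#' @return Numeric vector of t-values, one per coordinate.
#' @export
sample_volume_at <- function(coords, vol) {
  stopifnot(inherits(vol, "atrophy_volume"))
  coords <- coerce_coords(coords)
  if (any(!is.finite(coords))) abort("`coords` must be finite.")
  n <- nrow(coords)
  if (n == 0) return(numeric(0))
  vox <- solve(vol$affine, rbind(t(coords), 1))[1:3, , drop = FALSE]
  idx <- round_half_away(vox) + 1  # to 1-based array indices
  dims <- dim(vol$grid)
  oob <- idx[1, ] < 1 | idx[1, ] > dims[1] |
    idx[2, ] < 1 | idx[2, ] > dims[2] |
    idx[3, ] < 1 | idx[3, ] > dims[3]
  if (any(oob)) {
    i <- which(oob)[1]
    abort(sprintf(
      "coordinate (%.2f, %.2f, %.2f) maps outside the %s grid of map '%s'.",
      coords[i, 1], coords[i, 2], coords[i, 3],
      paste(dims, collapse = "x"), vol$map_id
    ))
  }
  vol$grid[cbind(idx[1, ], idx[2, ], idx[3, ])]
}

coerce_coords <- function(coords) {
  if (is.data.frame(coords)) {
    need <- c("mni_x", "mni_y", "mni_z")
    if (!all(need %in% names(coords))) {
      abort("data-frame `coords` needs columns mni_x, mni_y, mni_z.")
    }
    coords <- as.matrix(coords[need])
  }
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) abort("`coords` must have three columns.")
  storage.mode(coords) <- "double"
  coords
}

#' Link every expression sample to its atrophy t-scores
#'
#' Looks up each sample's coordinate in every supplied volume, yielding the
#' samples x maps matrix of t-values the association stage consumes.
#'
#' @param samples Data frame with `sample_id` and `mni_x`/`mni_y`/`mni_z`
#'   columns.
#' @param volumes List of [atrophy_volume()]s with distinct `map_id`s.
#' @return Tibble with `sample_id` and one t-value column per map.
#' @examples
#' aff <- diag(4)
#' vol <- generate_atrophy_volume(c(10, 10, 10), aff, c(5, 5, 5), 3, 5,
#'                                map_id = "C9orf72")
#' s <- tibble::tibble(sample_id = "s1", mni_x = 5, mni_y = 5, mni_z = 5)
#' build_sample_atrophy_table(s, list(vol))
#' @export
build_sample_atrophy_table <- function(samples, volumes) {
  ids <- vapply(volumes, function(v) v$map_id, character(1))
  if (anyDuplicated(ids)) abort("volumes must have distinct `map_id`s.")
  out <- tibble::tibble(sample_id = samples$sample_id)
  for (v in volumes) {
    out[[v$map_id]] <- sample_volume_at(samples, v)
  }
  out
}
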