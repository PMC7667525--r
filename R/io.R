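# File-format interfaces: Allen-style CSV bundles, NIfTI volumes, GMT gene
# sets, FPKM TSV tables.

#' Write / read an expression bundle as CSV files
#'
#' The on-disk dialect mirrors Allen-style bundles: `samples.csv` (annotation),
#' `probes.csv` (annotation), `expression.csv` (probe x sample values with a
#' `probe_id` key column) and `expressed.csv` (0/1 flags, same shape).
#'
#' @param bundle An [expression_bundle()].
#' @param dir Directory to create/fill.
#' @return `dir`, invisibly (writer); an `expression_bundle` (reader).
#' @export
write_expression_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "expression_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(bundle$samples, file.path(dir, "samples.csv"))
  readr::write_csv(bundle$probes, file.path(dir, "probes.csv"))
  mat_tbl <- function(m) {
    dplyr::bind_cols(tibble::tibble(probe_id = rownames(m)),
                     tibble::as_tibble(as.data.frame(m)))
  }
  readr::write_csv(mat_tbl(bundle$expr), file.path(dir, "expression.csv"))
  readr::write_csv(mat_tbl(bundle$expressed * 1L), file.path(dir, "expressed.csv"))
  invisible(dir)
}

#' @rdname write_expression_bundle
#' @export
read_expression_bundle <- function(dir) {
  samples <- readr::read_csv(file.path(dir, "samples.csv"),
                             show_col_types = FALSE)
  probes <- readr::read_csv(file.path(dir, "probes.csv"),
                            show_col_types = FALSE)
  read_mat <- function(f) {
    tbl <- readr::read_csv(file.path(dir, f), show_col_types = FALSE)
    m <- as.matrix(tbl[-1])
    rownames(m) <- tbl$probe_id
    m
  }
  expression_bundle(samples, probes, read_mat("expression.csv"),
                    read_mat("expressed.csv") > 0)
}

#' Write / read an atrophy volume as NIfTI-1
#'
#' The affine is stored as the sform (code 2); on reading, the image's xform
#' supplies the voxel-to-world map.
#'
#' @param vol An [atrophy_volume()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @param map_id Map label to attach on reading (default: file stem).
#' @return `path`, invisibly (writer); an `atrophy_volume` (reader).
#' @export
write_atrophy_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "atrophy_volume"))
  im <- RNifti::asNifti(vol$grid)
  RNifti::sform(im) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @rdname write_atrophy_nifti
#' @export
read_atrophy_nifti <- function(path, map_id = NULL) {
  im <- RNifti::readNifti(path)
  if (is.null(map_id)) {
    map_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  aff <- unclass(RNifti::xform(im))
  attributes(aff) <- list(dim = c(4L, 4L))
  atrophy_volume(array(as.numeric(im), dim = dim(im)), aff, map_id)
}

#' Read / write GMT gene-set collections
#'
#' @param path GMT file path.
#' @param sets Named list of character vectors.
#' @param description Description field written as the second GMT column.
#' @return Named list of character vectors (reader); `path`, invisibly
#'   (writer).
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- purrr::imap_chr(sets, function(genes, nm) {
    paste(c(nm, description, genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a genes x cell-types FPKM table as TSV
#'
#' @param path TSV path; first column `gene`, one column per cell type.
#' @param tbl Tibble as produced by [generate_marker_table()].
#' @return Tibble (reader); `path`, invisibly (writer).
#' @export
read_fpkm <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_fpkm
#' @export
write_fpkm <- function(tbl, path) {
  readr::write_tsv(tbl, path)
  invisible(path)
}
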