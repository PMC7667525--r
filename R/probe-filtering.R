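#' Select left-hemisphere cortical samples near the cortical ROI
#'
#' Retains a sample iff it is from the left hemisphere, comes from a
#' "cortex" slab, lies within `max_dist` mm (inclusive) of a cortical region
#' of interest, and is not annotated with a non-cortical structure label.
#' Row order is preserved.
#'
#' @param samples Data frame with columns `hemisphere`, `slab_type`,
#'   `dist_to_cortex_roi` and `structure_label`.
#' @param max_dist Maximum distance to the cortical ROI, mm (inclusive).
#' @param noncortical_labels Structure labels to exclude (e.g. "CA1 field").
#' @return Tibble of retained samples.
#' @export
select_cortical_samples <- function(samples, max_dist = 3,
                                    noncortical_labels = character()) {
  need <- c("hemisphere", "slab_type", "dist_to_cortex_roi", "structure_label")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols) > 0) {
    abort(sprintf("`samples` lacks columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  samples |>
    tibble::as_tibble() |>
    dplyr::filter(
      .data$hemisphere == "left",
      .data$slab_type == "cortex",
      .data$dist_to_cortex_roi <= max_dist,
      !.data$structure_label %in% noncortical_labels
    )
}

#' Partition probes by mapping status
#'
#' Retains uniquely mapped probes and partitions the exclusions by reason
#' (multi-gene, intergenic, unmappable). Partition sizes always sum to the
#' input size.
#'
#' @param probes Data frame with a `mapping_status` column taking values
#'   `unique`, `multi_gene`, `intergenic` or `unmapped`.
#' @return Named list of tibbles: `retained`, `excluded_multi`,
#'   `excluded_intergenic`, `excluded_unmapped`.
#' @export
classify_probes <- function(probes) {
  probes <- tibble::as_tibble(probes)
  statuses <- c("unique", "multi_gene", "intergenic", "unmapped")
  bad <- setdiff(unique(probes$mapping_status), statuses)
  if (length(bad) > 0) {
    abort(sprintf("unknown mapping_status value(s): %s",
                  paste(bad, collapse = ", ")))
  }
  split_by <- function(s) dplyr::filter(probes, .data$mapping_status == s)
  list(
    retained = split_by("unique"),
    excluded_multi = split_by("multi_gene"),
    excluded_intergenic = split_by("intergenic"),
    excluded_unmapped = split_by("unmapped")
  )
}

#' Remove probes expressed in too few samples
#'
#' A probe is dropped iff it is flagged expressed in strictly fewer than
#' `min_samples` samples; a probe at exactly the threshold is retained.
#'
#' @param probes Data frame with an `n_expressed_samples` column.
#' @param min_samples Minimum number of expressed samples.
#' @return Tibble of retained probes.
#' @export
filter_low_expression <- function(probes, min_samples = 300) {
  if (!"n_expressed_samples" %in% names(probes)) {
    abort("`probes` lacks an `n_expressed_samples` column.")
  }
  probes |>
    tibble::as_tibble() |>
    dplyr::filter(.data$n_expressed_samples >= min_samples)
}

#' Summarise the probe-filter bookkeeping
#'
#' @param classified Output of [classify_probes()].
#' @param expressed Output of [filter_low_expression()] applied to the
#'   retained partition (optional).
#' @return Tibble with one row per category and its probe count, suitable for
#'   writing as a filter-report TSV.
#' @export
filter_report <- function(classified, expressed = NULL) {
  out <- tibble::tibble(
    category = names(classified),
    n_probes = unname(vapply(classified, nrow, integer(1))),
    n_genes = unname(vapply(classified, function(x) {
      dplyr::n_distinct(x$gene_symbol, na.rm = TRUE)
    }, integer(1)))
  )
  if (!is.null(expressed)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      category = "retained_expressed",
      n_probes = nrow(expressed),
      n_genes = dplyr::n_distinct(expressed$gene_symbol, na.rm = TRUE)
    ))
  }
  out
}
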