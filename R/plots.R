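# ggplot2 views of the result types.

#' Volcano-style view of combined probe associations
#'
#' Combined Z against -log10 FDR q, per map; probes crossing the FDR
#' threshold are highlighted.
#'
#' @param probe_assoc Probe-level tibble (`tidy()` of an `atrocor_result`, or
#'   the result itself).
#' @param threshold FDR threshold to highlight.
#' @return A ggplot.
#' @export
plot_association <- function(probe_assoc, threshold = 0.05) {
  if (inherits(probe_assoc, "atrocor_result")) {
    probe_assoc <- probe_assoc$probe_assoc
  }
  probe_assoc |>
    dplyr::mutate(significant = .data$q < threshold) |>
    ggplot2::ggplot(ggplot2::aes(.data$z_meta, -log10(.data$q),
                                 colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$map_id)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "combined Z (Stouffer, signed weights)",
                  y = expression(-log[10] ~ q), colour = "FDR < threshold") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.atrocor_result <- function(object, ...) {
  plot_association(object, threshold = object$params$threshold)
}

#' Dot plot of overrepresentation results
#'
#' @param enrich Tibble from [fisher_ora()].
#' @param top_n Number of sets (smallest q) to show.
#' @return A ggplot.
#' @export
plot_enrichment <- function(enrich, top_n = 15) {
  enrich |>
    dplyr::slice_min(.data$q, n = top_n, with_ties = FALSE) |>
    dplyr::mutate(set = stats::reorder(.data$set, .data$odds_ratio)) |>
    ggplot2::ggplot(ggplot2::aes(.data$odds_ratio, .data$set,
                                 size = .data$a, colour = -log10(.data$q))) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::labs(x = "odds ratio", y = NULL, size = "overlap",
                  colour = expression(-log[10] ~ q)) +
    ggplot2::theme_minimal()
}

#' Map the leading Moran eigenvectors over a donor's samples
#'
#' Colours each sample by its loading on the first few eigenvectors — the
#' smooth spatial patterns the regression uses as confound covariates.
#'
#' @param basis An [compute_mem()] basis.
#' @param geom The matching [donor_geometry()].
#' @param n_vectors How many leading eigenvectors to draw.
#' @return A ggplot (samples shown in the x-y world plane).
#' @export
plot_mem <- function(basis, geom, n_vectors = 4) {
  n_vectors <- min(n_vectors, ncol(basis$vectors))
  tbl <- purrr::map(seq_len(n_vectors), function(i) {
    tibble::tibble(
      eigenvector = sprintf("MEM %d (lambda = %.2f)", i, basis$values[i]),
      x = geom$coords[, 1], y = geom$coords[, 2],
      loading = basis$vectors[, i]
    )
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(tbl, ggplot2::aes(.data$x, .data$y,
                                    colour = .data$loading)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$eigenvector)) +
    ggplot2::scale_colour_gradient2() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}
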