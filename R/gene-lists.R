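#' Collapse probe-level calls to signed gene lists
#'
#' A gene enters the positive list iff any probe targeting it has FDR q below
#' the threshold and a positive combined Z; likewise for the negative list
#' with a negative Z. Under this any-probe rule a gene with discordant
#' significant probes appears in both lists.
#'
#' @param assoc Data frame of probe-level results for one map, with columns
#'   `probe_id`, `z_meta`, `q`.
#' @param probe_gene_map Data frame with `probe_id` and `gene_symbol`
#'   covering every probe in `assoc`.
#' @param threshold FDR threshold.
#' @return A `gene_lists` object: list with character vectors `positive` and
#'   `negative`.
#' @export
probe_to_gene_lists <- function(assoc, probe_gene_map, threshold = 0.05) {
  joined <- dplyr::left_join(
    tibble::as_tibble(assoc),
    dplyr::distinct(tibble::as_tibble(probe_gene_map),
                    .data$probe_id, .data$gene_symbol),
    by = "probe_id"
  )
  if (any(is.na(joined$gene_symbol))) {
    bad <- joined$probe_id[is.na(joined$gene_symbol)][1]
    abort(sprintf("probe '%s' has no gene mapping.", bad))
  }
  sig <- dplyr::filter(joined, .data$q < threshold)
  structure(
    list(
      positive = sort(unique(sig$gene_symbol[sig$z_meta > 0])),
      negative = sort(unique(sig$gene_symbol[sig$z_meta < 0]))
    ),
    class = "gene_lists"
  )
}

#' @export
print.gene_lists <- function(x, ...) {
  cat(sprintf("<gene_lists> %d positive, %d negative genes\n",
              length(x$positive), length(x$negative)))
  invisible(x)
}

#' Consensus gene lists across the three atrophy maps
#'
#' Intersects the per-map positive lists into a positive consensus, and the
#' per-map negative lists into a negative consensus.
#'
#' @param per_map List of exactly three [probe_to_gene_lists()] results.
#' @return List with `consensus_positive` and `consensus_negative` character
#'   vectors.
#' @export
consensus_lists <- function(per_map) {
  if (length(per_map) != 3) {
    abort(sprintf("consensus is defined over exactly 3 maps, got %d.",
                  length(per_map)))
  }
  list(
    consensus_positive = sort(Reduce(intersect,
                                     lapply(per_map, `[[`, "positive"))),
    consensus_negative = sort(Reduce(intersect,
                                     lapply(per_map, `[[`, "negative")))
  )
}
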