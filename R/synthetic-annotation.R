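#' Generate a probe annotation table with prescribed mapping-status counts
#'
#' Emulates the output of sequence-level probe reannotation: every probe is
#' classified as uniquely mapped to one gene, mapped to multiple genes,
#' intergenic, or unmappable. Category counts are exact; uniquely mapped
#' probes cover exactly `n_genes` gene symbols (each gene gets at least one
#' probe).
#'
#' @param n_total Total probes.
#' @param n_multi,n_intergenic,n_unmapped Probes per exclusion category.
#' @param n_genes Distinct gene symbols covered by the uniquely mapped
#'   probes; at most `n_total - n_multi - n_intergenic - n_unmapped`.
#' @param seed Integer seed.
#' @return Tibble with `probe_id`, `mapping_status`, `gene_symbol` (`NA`
#'   unless uniquely mapped).
#' @examples
#' generate_probe_annotation(100, 5, 10, 5, n_genes = 40, seed = 1)
#' @export
generate_probe_annotation <- function(n_total, n_multi, n_intergenic,
                                      n_unmapped, n_genes, seed) {
  n_total <- check_count(n_total, "n_total")
  n_multi <- check_count(n_multi, "n_multi", min = 0)
  n_intergenic <- check_count(n_intergenic, "n_intergenic", min = 0)
  n_unmapped <- check_count(n_unmapped, "n_unmapped", min = 0)
  n_genes <- check_count(n_genes, "n_genes")
  n_unique <- n_total - n_multi - n_intergenic - n_unmapped
  if (n_unique < 0) {
    abort("exclusion categories exceed `n_total`.")
  }
  if (n_unique < n_genes) {
    abort("fewer uniquely mapped probes than `n_genes`; cannot cover all genes.")
  }
  withr::with_seed(seed, {
    status <- sample(rep(
      c("unique", "multi_gene", "intergenic", "unmapped"),
      times = c(n_unique, n_multi, n_intergenic, n_unmapped)
    ))
    genes <- gene_ids(n_genes)
    # each gene once, remaining unique probes drawn with replacement
    assignment <- sample(c(genes, sample(genes, n_unique - n_genes,
                                         replace = TRUE)))
    out <- tibble::tibble(
      probe_id = make_ids("P", n_total),
      mapping_status = status,
      gene_symbol = NA_character_
    )
    out$gene_symbol[out$mapping_status == "unique"] <- assignment
    out
  })
}

#' Generate a cell-type mean-expression (FPKM) table
#'
#' Produces a genes x cell-types table of nonnegative FPKM values in which a
#' designated block of genes per cell type is strongly enriched (target FPKM
#' at least three times the mean over the other types and above typical
#' marker thresholds), so marker-derivation rules have known positives.
#'
#' @param n_genes Number of genes (rows); symbols are `gene_ids(n_genes)`.
#' @param cell_types Character vector of cell-type names (columns).
#' @param markers_per_type Designated marker genes per cell type.
#' @param seed Integer seed.
#' @return Tibble with a `gene` column and one FPKM column per cell type;
#'   attribute `marker_truth` is a named character vector mapping each
#'   designated marker gene to its cell type.
#' @export
generate_marker_table <- function(n_genes, cell_types, markers_per_type = 10,
                                  seed = 1) {
  n_genes <- check_count(n_genes, "n_genes")
  if (length(cell_types) == 0) abort("`cell_types` must be nonempty.")
  k <- length(cell_types)
  n_marked <- k * markers_per_type
  if (n_marked > n_genes) abort("too many designated markers for `n_genes`.")
  withr::with_seed(seed, {
    fpkm <- matrix(stats::rlnorm(n_genes * k, meanlog = 0.3, sdlog = 0.8),
                   n_genes, k, dimnames = list(NULL, cell_types))
    truth <- setNames(rep(cell_types, each = markers_per_type),
                      gene_ids(n_genes)[seq_len(n_marked)])
    for (i in seq_len(n_marked)) {
      type <- match(truth[[i]], cell_types)
      base <- mean(fpkm[i, -type])
      fpkm[i, type] <- max(3 * base, 3) * runif(1, 1.2, 2)
    }
    out <- tibble::as_tibble(as.data.frame(fpkm))
    out <- dplyr::bind_cols(tibble::tibble(gene = gene_ids(n_genes)), out)
    attr(out, "marker_truth") <- truth
    out
  })
}

#' Generate a gene-set collection over a universe
#'
#' @param n_sets Number of sets.
#' @param set_sizes Length-2 integer range of set sizes (inclusive).
#' @param universe Character vector of gene symbols to draw from.
#' @param seed Integer seed.
#' @return Named list of character vectors (sets `GS0001`, ...), each a
#'   subset of `universe`.
#' @export
generate_gene_sets <- function(n_sets, set_sizes, universe, seed = 1) {
  n_sets <- check_count(n_sets, "n_sets")
  if (length(universe) == 0) abort("`universe` must be nonempty.")
  if (length(set_sizes) != 2 || any(set_sizes < 1) ||
      max(set_sizes) > length(universe)) {
    abort("`set_sizes` must be a range within 1..|universe|.")
  }
  withr::with_seed(seed, {
    sizes <- sample(seq(set_sizes[1], set_sizes[2]), n_sets, replace = TRUE)
    sets <- purrr::map(sizes, ~ sample(universe, .x))
    names(sets) <- make_ids("GS", n_sets)
    sets
  })
}
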