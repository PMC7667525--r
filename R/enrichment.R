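#' Fisher's-exact overrepresentation of a gene list in set collections
#'
#' For each gene set, builds the 2x2 table against the background universe —
#' `a` = list members in the set, `b` = list members outside it, `c` = set
#' members not in the list, `d` = the rest of the background — and tests
#' overrepresentation with the one-sided (greater) hypergeometric tail. The
#' odds ratio is the sample (cross-product) estimate `a*d / (b*c)`, with 0.5
#' added to every cell iff any cell is zero (Haldane correction). Q-values
#' are Benjamini-Hochberg across all sets in the collection. List members
#' outside the background are dropped (with a message); sets are intersected
#' with the background before testing.
#'
#' @param gene_list Character vector of gene symbols (e.g. a consensus list).
#' @param collection Named list of gene sets (e.g. from [read_gmt()] or
#'   [generate_gene_sets()]); empty sets are not allowed.
#' @param background Character vector: the expressed-gene universe.
#' @return Tibble with one row per set: `set`, `n_set`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p`, `q`.
#' @examples
#' bg <- gene_ids(100)
#' fisher_ora(bg[1:10], list(S = bg[6:25]), bg)  # a = 5, OR = 5
#' @export
fisher_ora <- function(gene_list, collection, background) {
  background <- unique(background)
  if (length(background) == 0) abort("`background` is empty.")
  if (length(collection) == 0 || is.null(names(collection))) {
    abort("`collection` must be a nonempty named list of gene sets.")
  }
  if (any(lengths(collection) == 0)) abort("`collection` contains empty sets.")
  gene_list <- unique(gene_list)
  dropped <- setdiff(gene_list, background)
  if (length(dropped) > 0) {
    message(sprintf("dropping %d list gene(s) outside the background.",
                    length(dropped)))
    gene_list <- intersect(gene_list, background)
  }
  n_bg <- length(background)
  n_list <- length(gene_list)
  n_set <- vapply(collection, function(s) {
    length(intersect(unique(s), background))
  }, integer(1))
  a <- vapply(collection, function(s) {
    length(intersect(gene_list, intersect(unique(s), background)))
  }, integer(1))
  b <- n_list - a
  cc <- n_set - a
  d <- n_bg - n_list - cc
  # upper hypergeometric tail: P(overlap >= a)
  p <- phyper(a - 1, n_set, n_bg - n_set, n_list, lower.tail = FALSE)
  # Haldane 0.5 on every cell iff any cell of that table is zero
  shift <- 0.5 * (a == 0 | b == 0 | cc == 0 | d == 0)
  or <- ((a + shift) * (d + shift)) / ((b + shift) * (cc + shift))
  tibble::tibble(
    set = names(collection), n_set = n_set,
    a = unname(a), b = unname(b), c = unname(cc), d = unname(d),
    odds_ratio = unname(or), p = unname(p), q = bh_fdr(unname(p))
  )
}

#' Derive cell-type marker gene sets from a mean-expression table
#'
#' A gene is a marker for a cell type iff its FPKM in that type strictly
#' exceeds `fpkm_min` and its enrichment — FPKM in the target type divided by
#' the arithmetic mean FPKM over all other types — is at least `enr_min`.
#'
#' @param mean_expr Data frame with a `gene` column and one nonnegative FPKM
#'   column per cell type (at least two types), e.g. from
#'   [generate_marker_table()] or [read_fpkm()].
#' @param fpkm_min Expression floor, FPKM (strict).
#' @param enr_min Enrichment floor (inclusive).
#' @return Named list of character vectors, one marker set per cell type
#'   (empty sets dropped).
#' @examples
#' tbl <- tibble::tibble(gene = "g1", A = 9, B = 1, C = 2)
#' derive_marker_sets(tbl)  # g1 marks A: 9 > 2.5 and 9/1.5 = 6 >= 3
#' @export
derive_marker_sets <- function(mean_expr, fpkm_min = 2.5, enr_min = 3.0) {
  if (!"gene" %in% names(mean_expr)) abort("`mean_expr` needs a `gene` column.")
  types <- setdiff(names(mean_expr), "gene")
  if (length(types) < 2) {
    abort("need at least two cell types; the non-target mean is undefined otherwise.")
  }
  fpkm <- as.matrix(mean_expr[types])
  if (any(fpkm < 0)) abort("FPKM values must be nonnegative.")
  sets <- purrr::map(types, function(ty) {
    target <- fpkm[, ty]
    other <- rowMeans(fpkm[, setdiff(types, ty), drop = FALSE])
    enr <- ifelse(other > 0, target / other, ifelse(target > 0, Inf, NaN))
    mean_expr$gene[target > fpkm_min & !is.nan(enr) & enr >= enr_min]
  })
  names(sets) <- types
  sets[lengths(sets) > 0]
}
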