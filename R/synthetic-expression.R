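#' Declare the planted signal of a synthetic study
#'
#' Records which genes carry a planted monotone association with atrophy
#' (and at what Spearman magnitude and sign), and which genes are spatial
#' confounds: spatially autocorrelated expression with no atrophy link.
#' Downstream parameter-recovery checks compare pipeline calls against this
#' object.
#'
#' @param assoc_genes Character vector of planted gene symbols.
#' @param effect_rho Target Spearman magnitude(s) in (0, 1]; recycled to one
#'   value per planted gene.
#' @param direction Planted sign(s), +1 or -1; recycled likewise.
#' @param confound_genes Character vector of spatial-confound gene symbols;
#'   must be disjoint from `assoc_genes`.
#' @param seed Integer seed recorded for provenance.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(assoc_genes = character(), effect_rho = numeric(),
                         direction = 1, confound_genes = character(),
                         seed = NA_integer_) {
  if (length(intersect(assoc_genes, confound_genes)) > 0) {
    abort("`assoc_genes` and `confound_genes` must be disjoint.")
  }
  if (length(assoc_genes) > 0) {
    effect_rho <- rep_len(effect_rho, length(assoc_genes))
    direction <- rep_len(direction, length(assoc_genes))
    if (any(effect_rho <= 0 | effect_rho > 1)) {
      abort("`effect_rho` must lie in (0, 1].")
    }
    if (!all(direction %in% c(-1, 1))) abort("`direction` must be +1 or -1.")
    names(effect_rho) <- assoc_genes
    names(direction) <- assoc_genes
  }
  structure(
    list(assoc_genes = assoc_genes, effect_rho = effect_rho,
         direction = direction, confound_genes = confound_genes, seed = seed),
    class = "ground_truth"
  )
}

#' Gene symbols used by the expression generator
#'
#' @param n Number of genes.
#' @return Character vector `G0001`, `G0002`, ...
#' @export
gene_ids <- function(n) make_ids("G", n)

#' Generate a per-donor expression bundle with planted associations
#'
#' Each gene's latent profile is a spatially autocorrelated Gaussian-process
#' draw (squared-exponential covariance over the donor's geodesic distances,
#' length-scale `range_mm`) plus white noise. For planted genes the latent is
#' instead a rank-based mixture with the atrophy scores: normal scores of the
#' atrophy ranks are blended with the (standardised) spatial+noise component
#' at the Pearson weight `2*sin(pi*rho/6)` that yields a marginal Spearman
#' correlation of about `rho` — the injection acts on ranks, so the target is
#' a Spearman, not Pearson, association. Probes replicate their gene's latent
#' plus independent probe noise; a probe is flagged "expressed" in a sample
#' when its value exceeds that probe's 25th percentile across samples,
#' mirroring the binary expression flags of Allen-style bundles.
#'
#' @param geom A `donor_geometry`.
#' @param n_genes Number of genes; symbols are `gene_ids(n_genes)`.
#' @param probes_per_gene Probes replicating each gene.
#' @param truth A [ground_truth()] naming planted/confound genes.
#' @param atrophy_t Numeric atrophy score per sample in `geom` (the planting
#'   reference; typically a sampled t-map or an average of several).
#' @param range_mm Gaussian-process length-scale, mm. `0` gives independent
#'   noise (no spatial structure).
#' @param noise_sd White-noise standard deviation added to the unit-variance
#'   spatial component.
#' @param probe_noise_sd Independent per-probe noise standard deviation.
#' @param seed Integer seed.
#' @return An `expression_bundle`: `samples` and `probes` tibbles plus
#'   probe x sample `expr` and logical `expressed` matrices.
#' @examples
#' geom <- generate_geometry(1, 40, seed = 1)[[1]]
#' tr <- ground_truth("G0001", effect_rho = 0.7, seed = 1)
#' b <- generate_expression(geom, 5, 2, tr, atrophy_t = rnorm(40),
#'                          range_mm = 10, noise_sd = 0.3, seed = 1)
#' b$probes
#' @export
generate_expression <- function(geom, n_genes, probes_per_gene, truth,
                                atrophy_t, range_mm, noise_sd,
                                probe_noise_sd = 0.2, seed = 1) {
  stopifnot(inherits(geom, "donor_geometry"), inherits(truth, "ground_truth"))
  n_genes <- check_count(n_genes, "n_genes")
  probes_per_gene <- check_count(probes_per_gene, "probes_per_gene")
  n <- nrow(geom$coords)
  if (length(atrophy_t) != n) {
    abort(sprintf("`atrophy_t` has %d values but `geom` has %d samples.",
                  length(atrophy_t), n))
  }
  genes <- gene_ids(n_genes)
  unknown <- setdiff(c(truth$assoc_genes, truth$confound_genes), genes)
  if (length(unknown) > 0) {
    abort(sprintf("ground truth names genes absent from this bundle: %s",
                  paste(head(unknown, 3), collapse = ", ")))
  }

  withr::with_seed(seed, {
    # one kernel square root serves every gene's spatial draw; geodesic
    # distances need not embed in Euclidean space, so the kernel can have
    # small negative eigenvalues — clip them instead of Cholesky
    spatial <- if (range_mm > 0) {
      kern <- exp(-geom$dist^2 / (2 * range_mm^2))
      eig <- eigen(kern, symmetric = TRUE)
      root <- eig$vectors %*% (sqrt(pmax(eig$values, 0)) * t(eig$vectors))
      root %*% matrix(rnorm(n * n_genes), n, n_genes)
    } else {
      matrix(rnorm(n * n_genes), n, n_genes)
    }
    latent <- spatial + matrix(rnorm(n * n_genes, sd = noise_sd), n, n_genes)
    colnames(latent) <- genes

    if (length(truth$assoc_genes) > 0) {
      # normal scores of the atrophy ranks: the monotone planting reference
      a <- qnorm((rank(atrophy_t, ties.method = "average") - 0.5) / n)
      a <- (a - mean(a)) / sd(a)
      for (g in truth$assoc_genes) {
        r_pearson <- 2 * sin(pi * truth$effect_rho[[g]] / 6)
        e <- latent[, g]
        e <- (e - mean(e)) / sd(e)
        latent[, g] <- truth$direction[[g]] * r_pearson * a +
          sqrt(1 - r_pearson^2) * e
      }
    }

    n_probes <- n_genes * probes_per_gene
    probe_gene <- rep(genes, each = probes_per_gene)
    expr <- t(latent[, probe_gene, drop = FALSE]) +
      matrix(rnorm(n_probes * n, sd = probe_noise_sd), n_probes, n)
    # probe identifiers are donor-independent, as in real multi-donor
    # bundles, so per-donor results can be combined per probe
    probe_id <- make_ids("P", n_probes)
    dimnames(expr) <- list(probe_id, rownames(geom$coords))

    q25 <- apply(expr, 1, quantile, probs = 0.25, names = FALSE)
    expressed <- expr > q25

    samples <- tibble::tibble(
      sample_id = rownames(geom$coords),
      donor_id = geom$donor_id,
      mni_x = geom$coords[, 1], mni_y = geom$coords[, 2],
      mni_z = geom$coords[, 3],
      slab_type = "cortex",
      structure_label = "synthetic cortex",
      hemisphere = "left",
      dist_to_cortex_roi = 0
    )
    probes <- tibble::tibble(
      probe_id = probe_id,
      mapping_status = "unique",
      gene_symbol = probe_gene,
      n_expressed_samples = as.integer(rowSums(expressed))
    )
    new_expression_bundle(samples, probes, expr, expressed)
  })
}

new_expression_bundle <- function(samples, probes, expr, expressed) {
  structure(
    list(samples = samples, probes = probes, expr = expr,
         expressed = expressed),
    class = "expression_bundle"
  )
}

#' Assemble an expression bundle from its parts
#'
#' @param samples Sample annotation tibble (one row per sample; must carry
#'   `sample_id`).
#' @param probes Probe annotation tibble (one row per probe; must carry
#'   `probe_id`).
#' @param expr Probe x sample numeric matrix.
#' @param expressed Optional logical matrix of the same shape; defaults to
#'   all `TRUE`.
#' @return An `expression_bundle`.
#' @export
expression_bundle <- function(samples, probes, expr, expressed = NULL) {
  expr <- as.matrix(expr)
  if (nrow(expr) != nrow(probes) || ncol(expr) != nrow(samples)) {
    abort("`expr` must be probes x samples.")
  }
  if (is.null(expressed)) {
    expressed <- matrix(TRUE, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  }
  if (!identical(dim(expressed), dim(expr))) {
    abort("`expressed` must match `expr` in shape.")
  }
  new_expression_bundle(tibble::as_tibble(samples), tibble::as_tibble(probes),
                        expr, expressed)
}

#' @export
print.expression_bundle <- function(x, ...) {
  cat(sprintf(
    "<expression_bundle> %s: %d probes x %d samples (%d genes)\n",
    x$samples$donor_id[1], nrow(x$expr), ncol(x$expr),
    dplyr::n_distinct(x$probes$gene_symbol, na.rm = TRUE)
  ))
  invisible(x)
}
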