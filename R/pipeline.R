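#' Simulate a complete imaging-transcriptomics study
#'
#' Wires the individual generators into one object holding everything the
#' association pipeline needs: donor geometries on a curved sheet, smooth
#' atrophy volumes (one per genetic-group map) sampled at every donor's
#' coordinates, and per-donor expression bundles in which a chosen subset of
#' genes carries a planted monotone association with atrophy. The planting
#' reference is the per-donor mean of the standardised map t-scores, so the
#' same genes associate with all maps (the consensus-list scenario); the
#' remaining genes are spatial confounds — autocorrelated expression with no
#' atrophy link.
#'
#' @param n_donors,n_samples,n_genes,probes_per_gene Study dimensions.
#' @param n_planted Number of genes with a planted association.
#' @param effect_rho Target Spearman magnitude of the planted genes.
#' @param map_ids Names of the atrophy maps; their Gaussian foci are offset
#'   from each other by `focus_jitter_mm` so the maps overlap strongly but
#'   are not identical.
#' @param focus_scale Gaussian radius of the atrophy bump, mm.
#' @param focus_jitter_mm Spread of the per-map focus offsets, mm.
#' @param peak_t Peak t-statistic of each map.
#' @param range_mm Expression length-scale, mm. The default 25 mm emulates
#'   the centimetre-scale regional gradients that dominate cortical
#'   expression maps.
#' @param noise_sd,probe_noise_sd Noise levels, see [generate_expression()];
#'   the default gives spatial and non-spatial expression variance equal
#'   weight.
#' @param t_field_range_mm,t_field_sd Spatially correlated noise added to the
#'   sampled atrophy scores (Gaussian-process length-scale, mm, and standard
#'   deviation): statistical maps from smoothed voxel-based morphometry carry
#'   spatially correlated noise on top of the anatomical signal, and this
#'   component is what lets the residual autocorrelation test see — and
#'   escalate away — shared smooth structure.
#' @param t_white_sd White sampling error added to the atrophy scores.
#' @param seed Integer seed; donor-level seeds are derived from it.
#' @return An `atrocor_study`: list with `geometries`, `volumes`, `bundles`,
#'   `atrophy` (per-donor tibbles of per-sample t-values), `truth`, `params`.
#' @examples
#' study <- simulate_study(n_donors = 2, n_samples = 60, n_genes = 20,
#'                         n_planted = 4, seed = 1)
#' @export
simulate_study <- function(n_donors = 6, n_samples = 200, n_genes = 500,
                           probes_per_gene = 1, n_planted = 50,
                           effect_rho = 0.6,
                           map_ids = c("C9orf72", "GRN", "MAPT"),
                           focus_scale = 25, focus_jitter_mm = 6,
                           peak_t = 6, range_mm = 25, noise_sd = 1.25,
                           probe_noise_sd = 0.2, t_field_range_mm = 10,
                           t_field_sd = 1, t_white_sd = 0.5, seed = 1) {
  if (n_planted > n_genes) abort("`n_planted` exceeds `n_genes`.")
  geometries <- generate_geometry(n_donors, n_samples, seed)

  # 2 mm isotropic grid generously covering the sheet's world extent
  affine <- diag(c(2, 2, 2, 1))
  affine[1:3, 4] <- c(-100, -55, -30)
  grid_shape <- c(52, 56, 31)
  center <- c(-45, 0, 0)
  volumes <- withr::with_seed(seed + 1L, {
    purrr::map(seq_along(map_ids), function(i) {
      generate_atrophy_volume(
        grid_shape, affine,
        focus_center = center + runif(3, -focus_jitter_mm, focus_jitter_mm),
        focus_scale = focus_scale, peak_t = peak_t, map_id = map_ids[i]
      )
    })
  })

  atrophy <- purrr::imap(geometries, function(geom, i) {
    withr::with_seed(seed + 100L + i, {
      n <- nrow(geom$coords)
      root <- if (t_field_sd > 0) {
        kern <- exp(-geom$dist^2 / (2 * t_field_range_mm^2))
        eig <- eigen(kern, symmetric = TRUE)
        eig$vectors %*% (sqrt(pmax(eig$values, 0)) * t(eig$vectors))
      }
      tbl <- tibble::tibble(sample_id = rownames(geom$coords))
      for (v in volumes) {
        tbl[[v$map_id]] <- sample_volume_at(geom$coords, v) +
          (if (t_field_sd > 0) t_field_sd * as.numeric(root %*% rnorm(n))
           else 0) +
          rnorm(n, sd = t_white_sd)
      }
      tbl
    })
  })

  genes <- gene_ids(n_genes)
  truth <- withr::with_seed(seed + 2L, {
    planted <- sort(sample(genes, n_planted))
    ground_truth(
      assoc_genes = planted, effect_rho = effect_rho,
      direction = rep_len(c(1, -1), n_planted),
      confound_genes = setdiff(genes, planted), seed = seed
    )
  })

  bundles <- purrr::imap(geometries, function(geom, i) {
    ref <- rowMeans(scale(as.matrix(atrophy[[i]][map_ids])))
    generate_expression(geom, n_genes, probes_per_gene, truth,
                        atrophy_t = ref, range_mm = range_mm,
                        noise_sd = noise_sd,
                        probe_noise_sd = probe_noise_sd,
                        seed = seed + 10L + i)
  })

  structure(
    list(
      geometries = geometries, volumes = volumes, bundles = bundles,
      atrophy = atrophy, truth = truth,
      params = list(n_donors = n_donors, n_samples = n_samples,
                    n_genes = n_genes, probes_per_gene = probes_per_gene,
                    effect_rho = effect_rho, range_mm = range_mm,
                    noise_sd = noise_sd, seed = seed)
    ),
    class = "atrocor_study"
  )
}

#' @export
print.atrocor_study <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<atrocor_study> %d donors x %d samples, %d genes (%d planted), %d map(s)\n",
    p$n_donors, p$n_samples, p$n_genes, length(x$truth$assoc_genes),
    length(x$volumes)
  ))
  invisible(x)
}

#' Run the spatially adjusted association analysis
#'
#' For every probe, donor and atrophy map: rank-regress the map's per-sample
#' t-scores on the probe's expression with Moran-eigenvector escalation
#' ([fit_with_sevm()]); combine donors per probe and map with sign-weighted
#' Stouffer's method; correct each map's meta p-values with
#' Benjamini-Hochberg across probes; collapse probes to signed gene lists
#' (any-probe rule) and, when exactly three maps are present, intersect them
#' into consensus lists. Probes with constant expression in a donor are
#' skipped for that donor; probes observed in fewer than two donors are
#' dropped from the combination.
#'
#' @param study An `atrocor_study` from [simulate_study()], or any list with
#'   `geometries`, `bundles` and `atrophy` of the same shape.
#' @param k Neighbours for the spatial graph.
#' @param alpha Residual Moran test level for eigenvector escalation.
#' @param cap Maximum eigenvectors per fit.
#' @param threshold FDR threshold for gene calls.
#' @param use_sevm If `FALSE`, fit plain rank regressions with no spatial
#'   adjustment (for diagnostics; the spatially naive analysis is
#'   anti-conservative).
#' @return An `atrocor_result`: `donor_assoc` (per donor x probe x map fits),
#'   `probe_assoc` (combined `z_meta`, `p_meta`, `q`, `direction`),
#'   `gene_lists` (per map), `consensus` (three-map studies),
#'   `eigenvector_summary`.
#' @examples
#' study <- simulate_study(n_donors = 2, n_samples = 60, n_genes = 15,
#'                         n_planted = 3, map_ids = "C9orf72", seed = 1)
#' res <- run_association(study)
#' res$probe_assoc
#' @export
run_association <- function(study, k = 10, alpha = 0.05, cap = 150,
                            threshold = 0.05, use_sevm = TRUE) {
  map_ids <- setdiff(names(study$atrophy[[1]]), "sample_id")
  donor_assoc <- purrr::imap(study$geometries, function(geom, di) {
    bundle <- study$bundles[[di]]
    graph <- if (use_sevm) build_knn_graph(geom$dist, k = k)
    basis <- if (use_sevm) compute_mem(graph)
    expr_ranks <- t(apply(bundle$expr, 1, rank_transform))
    keep <- apply(bundle$expr, 1, var) > 0
    purrr::map(map_ids, function(mid) {
      ry <- rank_transform(study$atrophy[[di]][[mid]])
      fits <- purrr::map(which(keep), function(pi) {
        f <- fit_sevm_ranks(ry, expr_ranks[pi, ], basis, graph,
                            alpha = alpha, cap = cap)
        tibble::tibble(
          probe_id = bundle$probes$probe_id[pi],
          estimate = f$estimate, statistic = f$statistic, p = f$p.value,
          n_eigenvectors = f$n_eigenvectors,
          residual_moran_p = f$residual_moran_p
        )
      })
      dplyr::bind_rows(fits) |>
        dplyr::mutate(donor_id = geom$donor_id, map_id = mid,
                      .before = 1)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  probe_assoc <- donor_assoc |>
    dplyr::group_by(.data$map_id, .data$probe_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(
      n_donors = dplyr::n(),
      z_meta = stouffer_z(.data$p, sign(.data$statistic)),
      .groups = "drop_last"
    ) |>
    dplyr::mutate(
      p_meta = 2 * pnorm(abs(.data$z_meta), lower.tail = FALSE),
      q = bh_fdr(.data$p_meta),  # per map, across that map's probes
      direction = sign(.data$z_meta)
    ) |>
    dplyr::ungroup()

  probe_gene_map <- study$bundles[[1]]$probes
  lists <- purrr::map(
    setNames(map_ids, map_ids),
    function(mid) {
      probe_to_gene_lists(dplyr::filter(probe_assoc, .data$map_id == mid),
                          probe_gene_map, threshold = threshold)
    }
  )
  consensus <- if (length(map_ids) == 3) consensus_lists(lists)

  ev <- donor_assoc$n_eigenvectors
  structure(
    list(
      donor_assoc = donor_assoc, probe_assoc = probe_assoc,
      gene_lists = lists, consensus = consensus,
      eigenvector_summary = c(
        min = min(ev), q1 = unname(quantile(ev, 0.25)),
        median = median(ev), q3 = unname(quantile(ev, 0.75)), max = max(ev)
      ),
      params = list(k = k, alpha = alpha, cap = cap, threshold = threshold,
                    use_sevm = use_sevm)
    ),
    class = "atrocor_result"
  )
}

#' @export
print.atrocor_result <- function(x, ...) {
  ev <- x$eigenvector_summary
  cat("<atrocor_result>\n")
  cat(sprintf(
    "  eigenvectors per fit: min %d, median %g (IQR %g-%g), max %d\n",
    ev["min"], ev["median"], ev["q1"], ev["q3"], ev["max"]
  ))
  counts <- glance(x)
  cat("  significant calls per map:\n")
  for (i in seq_len(nrow(counts))) {
    cat(sprintf("    %-10s probes +%d/-%d  genes +%d/-%d\n",
                counts$map_id[i], counts$probes_positive[i],
                counts$probes_negative[i], counts$genes_positive[i],
                counts$genes_negative[i]))
  }
  if (!is.null(x$consensus)) {
    cat(sprintf("  consensus: %d positive, %d negative genes\n",
                length(x$consensus$consensus_positive),
                length(x$consensus$consensus_negative)))
  }
  invisible(x)
}

#' @rdname run_association
#' @param x,object An `atrocor_result`.
#' @param ... Unused.
#' @export
tidy.atrocor_result <- function(x, ...) x$probe_assoc

#' @rdname run_association
#' @export
glance.atrocor_result <- function(x, ...) {
  thr <- x$params$threshold
  x$probe_assoc |>
    dplyr::group_by(.data$map_id) |>
    dplyr::summarise(
      probes_positive = sum(.data$q < thr & .data$z_meta > 0),
      probes_negative = sum(.data$q < thr & .data$z_meta < 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      genes_positive = lengths(purrr::map(x$gene_lists[.data$map_id],
                                          "positive")),
      genes_negative = lengths(purrr::map(x$gene_lists[.data$map_id],
                                          "negative"))
    )
}
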