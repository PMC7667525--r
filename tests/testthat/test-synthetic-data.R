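test_that("donor geometries are valid geodesic surrogates", {
  geoms <- generate_geometry(2, 40, seed = 1)
  expect_length(geoms, 2)
  for (g in geoms) {
    expect_identical(dim(g$dist), c(40L, 40L))
    expect_equal(g$dist, t(g$dist))
    expect_true(all(diag(g$dist) == 0))
  }
  # every off-diagonal distance strictly positive (distinct points)
  g <- generate_geometry(1, 30, seed = 7)[[1]]
  off <- g$dist[upper.tri(g$dist)]
  expect_true(all(off > 0))
  # shortest-path distances obey the triangle inequality
  n <- nrow(g$dist)
  viol <- 0
  for (i in 1:n) for (j in 1:n) {
    viol <- viol + sum(g$dist[i, ] + g$dist[, j] < g$dist[i, j] - 1e-9)
  }
  expect_equal(viol, 0)
})

test_that("geometry generation is deterministic and guards its sizing", {
  a <- generate_geometry(2, 25, seed = 5)
  b <- generate_geometry(2, 25, seed = 5)
  expect_identical(a, b)
  expect_error(generate_geometry(1, 10, seed = 1), "at least 20")
})

test_that("externally supplied distances are accepted and validated", {
  geom <- fixture_geom(30, seed = 3)
  custom <- donor_geometry("x", geom$coords, dist = geom$dist)
  expect_identical(custom$dist, geom$dist)
  bad <- geom$dist
  bad[1, 2] <- bad[1, 2] + 5  # break symmetry
  expect_error(donor_geometry("x", geom$coords, dist = bad), "symmetric")
})

test_that("planted genes reach their target Spearman correlation", {
  geom <- fixture_geom(200, seed = 21)
  tv <- rnorm(200)
  tr <- ground_truth("G0001", effect_rho = 0.7, seed = 1)
  b <- generate_expression(geom, 10, 1, tr, atrophy_t = tv, range_mm = 10,
                           noise_sd = 0.1, probe_noise_sd = 0.05, seed = 2)
  rho <- cor(b$expr["P0001", ], tv, method = "spearman")
  expect_gt(rho, 0.55)
  expect_lt(rho, 0.85)
  # a negative planted direction flips the sign
  trn <- ground_truth("G0001", effect_rho = 0.7, direction = -1, seed = 1)
  bn <- generate_expression(geom, 10, 1, trn, atrophy_t = tv, range_mm = 10,
                            noise_sd = 0.1, probe_noise_sd = 0.05, seed = 2)
  expect_lt(cor(bn$expr["P0001", ], tv, method = "spearman"), -0.55)
})

test_that("unplanted independent genes show no association", {
  geom <- fixture_geom(200, seed = 21)
  tv <- rnorm(200)
  tr <- ground_truth(seed = 1)
  b <- generate_expression(geom, 60, 1, tr, atrophy_t = tv, range_mm = 0,
                           noise_sd = 1, seed = 3)
  rhos <- apply(b$expr, 1, cor, y = tv, method = "spearman")
  expect_lt(mean(abs(rhos)), 2 / sqrt(200))
})

test_that("probes of one gene co-vary more than probes of different genes", {
  geom <- fixture_geom(100, seed = 12)
  tr <- ground_truth(seed = 1)
  b <- generate_expression(geom, 20, 2, tr, atrophy_t = rnorm(100),
                           range_mm = 15, noise_sd = 0.5, seed = 4)
  cc <- cor(t(b$expr))
  gene <- b$probes$gene_symbol
  same <- outer(gene, gene, "==") & upper.tri(cc)
  diff <- outer(gene, gene, "!=") & upper.tri(cc)
  expect_gt(mean(cc[same]), mean(cc[diff]))
})

test_that("expression generator validates lengths and flags expression", {
  geom <- fixture_geom(30, seed = 3)
  tr <- ground_truth(seed = 1)
  expect_error(
    generate_expression(geom, 5, 1, tr, atrophy_t = rnorm(10),
                        range_mm = 5, noise_sd = 1, seed = 1),
    "10 values"
  )
  b <- generate_expression(geom, 5, 1, tr, atrophy_t = rnorm(30),
                           range_mm = 5, noise_sd = 1, seed = 1)
  # expressed iff above that probe's 25th percentile
  for (i in 1:5) {
    q <- quantile(b$expr[i, ], 0.25, names = FALSE)
    expect_identical(b$expressed[i, ], b$expr[i, ] > q)
  }
  expect_identical(b$probes$n_expressed_samples, as.integer(rowSums(b$expressed)))
})

test_that("planted-signal calibration holds over many genes", {
  geom <- fixture_geom(200, seed = 21)
  tv <- rnorm(200)
  genes <- gene_ids(100)
  tr <- ground_truth(genes, effect_rho = 0.6, seed = 1)
  b <- generate_expression(geom, 100, 1, tr, atrophy_t = tv, range_mm = 25,
                           noise_sd = 1.25, seed = 9)
  rhos <- apply(b$expr, 1, cor, y = tv, method = "spearman")
  expect_lt(abs(mean(abs(rhos)) - 0.6), 0.1)
})

test_that("confound genes are spatially autocorrelated on the 10-NN graph", {
  geom <- fixture_geom(200, seed = 21)
  d <- geom$dist
  diag(d) <- Inf
  rng <- 5 * median(apply(d, 1, min))
  tr <- ground_truth(confound_genes = gene_ids(50), seed = 1)
  b <- generate_expression(geom, 50, 1, tr, atrophy_t = rnorm(200),
                           range_mm = rng, noise_sd = 1.25, seed = 10)
  g <- build_knn_graph(geom$dist, k = 10)
  res <- apply(b$expr, 1, function(x) {
    m <- moran_I(x, g)
    c(m$I, m$p)
  })
  expect_gte(mean(res[1, ] > 0 & res[2, ] < 0.05), 0.9)
})

test_that("ground truth validates its inputs", {
  expect_error(ground_truth("G0001", 0.5, confound_genes = "G0001"),
               "disjoint")
  expect_error(ground_truth("G0001", 1.2), "0, 1")
  expect_error(ground_truth("G0001", 0.5, direction = 2), "\\+1 or -1")
})

test_that("atrophy volumes match their closed form", {
  aff <- diag(4)
  aff[1:3, 4] <- c(-10, -10, -10)
  vol <- generate_atrophy_volume(c(21, 21, 21), aff, focus_center = c(0, 0, 0),
                                 focus_scale = 4, peak_t = 5)
  # voxel containing the focus carries the peak
  expect_equal(vol$grid[11, 11, 11], 5)
  # far from the focus the bump vanishes
  expect_lt(vol$grid[1, 1, 1], 1e-3)
  # every voxel equals the formula evaluated at its world coordinate
  set.seed(1)
  for (r in 1:50) {
    ijk <- sapply(c(21, 21, 21), function(m) sample(m, 1))
    world <- (aff %*% c(ijk - 1, 1))[1:3]
    expect_equal(vol$grid[ijk[1], ijk[2], ijk[3]],
                 5 * exp(-sum(world^2) / (2 * 16)), tolerance = 1e-12)
  }
  expect_error(generate_atrophy_volume(c(5, 5, 5), matrix(0, 4, 4),
                                       c(0, 0, 0), 1, 1), "singular")
})

test_that("probe annotation tables honour requested counts", {
  tbl <- generate_probe_annotation(100, 5, 10, 5, n_genes = 40, seed = 1)
  expect_identical(sum(tbl$mapping_status == "unique"), 80L)
  expect_identical(sum(tbl$mapping_status == "multi_gene"), 5L)
  expect_identical(sum(tbl$mapping_status == "intergenic"), 10L)
  expect_identical(sum(tbl$mapping_status == "unmapped"), 5L)
  expect_identical(nrow(tbl), 100L)
  expect_identical(dplyr::n_distinct(tbl$gene_symbol, na.rm = TRUE), 40L)
  expect_true(all(is.na(tbl$gene_symbol[tbl$mapping_status != "unique"])))

  all_unique <- generate_probe_annotation(10, 0, 0, 0, n_genes = 3, seed = 1)
  expect_true(all(all_unique$mapping_status == "unique"))
  expect_identical(generate_probe_annotation(100, 5, 10, 5, 40, seed = 2),
                   generate_probe_annotation(100, 5, 10, 5, 40, seed = 2))
  expect_error(generate_probe_annotation(10, 5, 5, 5, 1, seed = 1), "exceed")
})

test_that("marker tables plant enriched genes and gene sets stay in-universe", {
  tbl <- generate_marker_table(100, c("neuron", "astro", "micro"),
                               markers_per_type = 5, seed = 2)
  truth <- attr(tbl, "marker_truth")
  fpkm <- as.matrix(tbl[-1])
  for (g in names(truth)) {
    i <- match(g, tbl$gene)
    ty <- truth[[g]]
    expect_gte(fpkm[i, ty], 3 * mean(fpkm[i, setdiff(colnames(fpkm), ty)]))
  }
  expect_identical(tbl, generate_marker_table(100, c("neuron", "astro", "micro"),
                                              markers_per_type = 5, seed = 2))
  uni <- gene_ids(50)
  sets <- generate_gene_sets(8, c(3, 10), uni, seed = 3)
  expect_true(all(unlist(sets) %in% uni))
  expect_identical(sets, generate_gene_sets(8, c(3, 10), uni, seed = 3))
  expect_error(generate_gene_sets(2, c(1, 5), character(), seed = 1),
               "nonempty")
})
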