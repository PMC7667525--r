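test_that("rank transform uses average ties and reproduces Spearman", {
  expect_equal(rank_transform(c(10, 20, 30)), c(1, 2, 3))
  expect_equal(rank_transform(c(5, 5, 9)), c(1.5, 1.5, 3))
  set.seed(2)
  x <- rnorm(50)
  y <- rnorm(50)
  expect_equal(cor(rank_transform(x), rank_transform(y)),
               cor(x, y, method = "spearman"), tolerance = 1e-12)
})

test_that("with zero eigenvectors the fit equals the classical Spearman test", {
  set.seed(7)
  for (r in 1:50) {
    n <- sample(20:80, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    fit <- fit_with_sevm(y, x, basis = NULL)
    oracle <- spearman_oracle(x, y)
    expect_identical(fit$n_eigenvectors, 0L)
    expect_lt(abs(fit$estimate - oracle$rho), 1e-10)
    expect_lt(abs(fit$statistic - oracle$t), 1e-10)
    expect_lt(abs(fit$p.value - oracle$p), 1e-10)
  }
})

test_that("escalation never triggers on spatially independent data", {
  g <- fixture_graph(60, seed = 11)
  basis <- compute_mem(g)
  set.seed(8)
  hits <- 0
  for (r in 1:20) {
    y <- rnorm(60)
    x <- rnorm(60)
    fit <- fit_with_sevm(y, x, basis, g)
    plain <- fit_with_sevm(y, x, basis = NULL)
    if (fit$n_eigenvectors == 0) {
      hits <- hits + 1
      expect_equal(fit$statistic, plain$statistic, tolerance = 1e-12)
      expect_gte(fit$residual_moran_p, 0.05)
    }
  }
  # the residual test runs at level 0.05, so the large majority never escalate
  expect_gte(hits, 15)
})

test_that("escalation follows the 0,1,5,10,... schedule and respects the cap", {
  g <- fixture_graph(200, seed = 21)
  basis <- compute_mem(g)
  # response made of positively autocorrelated eigenvectors beyond the cap:
  # residual autocorrelation persists at m = 10
  y <- as.numeric(basis$vectors[, 12:40] %*% rep(1, 29)) +
    rnorm(200, sd = 1e-3)
  set.seed(9)
  x <- rnorm(200)
  fit <- fit_with_sevm(y, x, basis, g, cap = 10)
  expect_identical(fit$n_eigenvectors, 10L)
  expect_lt(fit$residual_moran_p, 0.05)  # reported as-is at the cap
  # exit condition: clean residuals or the largest scheduled m
  fit2 <- fit_with_sevm(y, x, basis, g, cap = 150)
  expect_true(fit2$residual_moran_p >= 0.05 || fit2$n_eigenvectors == 150L)
  expect_true(fit2$n_eigenvectors %in% c(0, 1, seq(5, 150, 5)))
})

test_that("fit guards degenerate input", {
  expect_error(fit_with_sevm(rnorm(5), rnorm(4)), "same length")
  expect_error(fit_with_sevm(rnorm(5), rep(1, 5)), "constant")
  g <- fixture_graph(25, seed = 13)
  basis <- compute_mem(g)
  expect_error(fit_with_sevm(rnorm(25), rnorm(25), basis), "graph")
  # duplicated eigenvector column makes the design rank-deficient
  bad <- basis
  bad$vectors[, 2] <- bad$vectors[, 1]
  y <- bad$vectors[, 3] + rnorm(25, sd = 1e-3)
  expect_error(
    fit_with_sevm(y, rnorm(25), bad, g, schedule = c(5L)),
    "rank-deficient with m = 5"
  )
})

test_that("Stouffer combination matches its closed forms", {
  p2 <- 2 * pnorm(-2)
  six <- tibble::tibble(p = rep(p2, 6), statistic = rep(3, 6))
  res <- stouffer_combine(six)
  expect_equal(res$z_meta, 12 / sqrt(6), tolerance = 1e-12)
  expect_equal(res$z_meta, 4.8990, tolerance = 1e-4)

  balanced <- tibble::tibble(p = rep(p2, 6), statistic = c(1, 1, 1, -1, -1, -1))
  res0 <- stouffer_combine(balanced)
  expect_equal(res0$z_meta, 0)
  expect_equal(res0$p_meta, 1)

  expect_error(stouffer_combine(six[1, ]), "at least 2")
})

test_that("Stouffer matches a normal-quantile oracle on random input", {
  set.seed(10)
  for (r in 1:25) {
    p <- runif(6)
    s <- sample(c(-1, 1), 6, TRUE)
    got <- stouffer_combine(tibble::tibble(p = p, statistic = s))
    zi <- qnorm(1 - p / 2)
    z <- sum(s * zi) / sqrt(6)
    expect_equal(got$z_meta, z, tolerance = 1e-12)
    expect_equal(got$p_meta, 2 * (1 - pnorm(abs(z))), tolerance = 1e-12)
    # sign coherence: the combined sign is the sign of the weighted sum
    expect_identical(got$direction, sign(sum(s * zi)))
  }
})

test_that("extreme p-values are clamped before inversion", {
  d <- tibble::tibble(p = c(0, 1e-320), statistic = c(1, 1))
  res <- stouffer_combine(d)
  expect_true(is.finite(res$z_meta))
  expect_error(stouffer_combine(tibble::tibble(p = c(-0.1, 0.5),
                                               statistic = c(1, 1))),
               "0, 1")
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  # hand-applied step-up on an unordered vector
  p <- c(0.30, 0.01, 0.04, 0.80)
  m <- 4
  ord <- order(p)
  q_sorted <- rev(cummin(rev(m * p[ord] / seq_len(m))))
  expect_equal(bh_fdr(p)[ord], pmin(q_sorted, 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("gene lists follow the any-probe rule", {
  pg <- tibble::tibble(probe_id = c("p1", "p2", "p3", "p4"),
                       gene_symbol = c("A", "B", "B", "C"))
  assoc <- tibble::tibble(
    probe_id = c("p1", "p2", "p3", "p4"),
    z_meta = c(3, 3, -4, 2),
    q = c(0.01, 0.01, 0.02, 0.5)
  )
  gl <- probe_to_gene_lists(assoc, pg)
  expect_identical(gl$positive, c("A", "B"))
  expect_identical(gl$negative, "B")  # discordant probes put B in both lists
  expect_false("C" %in% c(gl$positive, gl$negative))
  expect_error(
    probe_to_gene_lists(tibble::tibble(probe_id = "px", z_meta = 1, q = 0.01),
                        pg),
    "no gene mapping"
  )
})

test_that("consensus lists intersect exactly three maps", {
  gl <- function(pos, neg = character()) {
    structure(list(positive = pos, negative = neg), class = "gene_lists")
  }
  cons <- consensus_lists(list(gl(c("A", "B", "C")), gl(c("B", "C")),
                               gl(c("B", "C", "D"))))
  expect_identical(cons$consensus_positive, c("B", "C"))
  expect_identical(cons$consensus_negative, character(0))
  expect_error(consensus_lists(list(gl("A"), gl("A"))), "exactly 3")
})
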