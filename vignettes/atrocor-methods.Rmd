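---
title: "Methods: spatially adjusted atrophy–expression association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatially adjusted atrophy-expression association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atrocor)
```

## The model

`atrocor` estimates, per microarray probe and per donor brain, the monotone
association between a probe's regional expression and the local burden of
grey-matter atrophy, while explicitly absorbing the spatial autocorrelation
that both fields carry. The unit of analysis is a cortical tissue sample with
an MNI coordinate; the atrophy side is the t-value of the voxel containing
that coordinate in a voxel-based-morphometry (VBM) contrast map.

The estimator is a rank regression. With $r(\cdot)$ the average-tie rank
transform, we fit

$$ r(t_i) = \beta_0 + \beta_1\, r(x_i) + \sum_{j=1}^{m} \gamma_j v_{ij} + \varepsilon_i $$

where $t_i$ is the sampled atrophy t-score, $x_i$ the probe's expression and
$v_{\cdot j}$ the leading Moran eigenvector maps (MEM) of the donor's spatial
weight matrix. With $m = 0$ and no ties, $\hat\beta_1$ *is* Spearman's
$\rho$ and its t-test is the classical Spearman test (the suite verifies
agreement to $10^{-10}$); the eigenvectors generalise this to a spatially
adjusted rank correlation.

Assumptions worth stating: the autocorrelation is treated as stationary
across the cortex (Moran's I is a global statistic); samples within a donor
share one spatial structure, and donors are independent; the monotone
association is assumed common in direction across donors but not in strength.

### Spatial machinery

The spatial weights come from the 10-nearest-neighbour graph over geodesic
(along-surface) inter-sample distances: $i \sim j$ iff either is among the
other's ten nearest (union symmetrisation), binary adjacency, then
row-standardised — the default conventions of the standard spatial-statistics
tooling. Residual autocorrelation is tested with Moran's I,

$$ I = \frac{n}{S_0}\,\frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2},
   \qquad E[I] = -\tfrac{1}{n-1}, $$

using the randomisation (permutation-moment) variance and a one-sided
"greater" alternative: positive residual autocorrelation is the failure mode
that invalidates the regression's standard errors. The MEM basis is the
eigendecomposition of $C \tilde W C$ with $C = I - \mathbf{1}\mathbf{1}'/n$
and $\tilde W = (W + W')/2$, eigenvalues descending, so the first vectors are
the smoothest spatial patterns; the first eigenvector attains the maximum
Moran's I achievable by any centered vector on the graph. Eigenvectors with
$|\lambda| < 10^{-12} \lambda_{\max}$ are dropped (this removes the constant
pattern). Negative-eigenvalue vectors are kept at the tail of the ordering;
under the escalation cap they are effectively never used, which matches their
role — they model negative autocorrelation, not the smooth confounding being
removed.

### Escalation schedule

Fits start with $m = 0$. While the residual Moran test has $p < 0.05$, $m$
escalates along $\{0, 1, 5, 10, 15, \dots, 150\}$: a single eigenvector
first, then batches of five, capped at 150 (and at $n - 3$ so at least two
residual degrees of freedom remain). On every completed fit either the
residuals are clean ($p \ge 0.05$) or the cap was reached, and the residual
p-value is reported as-is — an assertable invariant. The per-fit eigenvector
count is part of the result (`eigenvector_summary`, and per fit in
`donor_assoc`).

### Combining donors and calling genes

Per probe and map, donor results are combined with Stouffer's weighted sum of
Z-scores with weights restricted to $\pm 1$ — the direction of each donor's
coefficient — so a donor with 1,000 samples counts no more than one with 200:
$Z_i = \Phi^{-1}(1 - p_i/2)$, $z_{\text{meta}} = \sum_i w_i Z_i / \sqrt{\sum w_i^2}$,
two-sided $p_{\text{meta}}$. P-values are clamped to
$[10^{-300}, 1 - 10^{-16}]$ before inversion. Probes with constant expression
in a donor are skipped for that donor and the denominator shrinks
accordingly; fewer than two donors drops the probe. Benjamini–Hochberg
correction is applied per map across that map's probes (three separate
corrections). A gene is called if *any* of its probes passes $q < 0.05$, with
the sign of $z_{\text{meta}}$ deciding the list; discordant significant probes
legitimately place a gene in both lists. Consensus lists intersect the three
per-map lists per sign.

### Overrepresentation

Gene lists are tested against a declared background (the expressed genes)
with the one-sided hypergeometric tail ($P(\text{overlap} \ge a)$), the
sample odds ratio $ad/bc$ with a Haldane 0.5 added to every cell iff any cell
is zero, and BH correction across the whole collection in one pass. The
conditional-MLE odds ratio some Fisher implementations report differs
slightly; the sample estimator is used here and documented as such. Cell-type
marker sets are derived from a genes × cell-types FPKM table: marker iff
FPKM strictly exceeds 2.5 in the target type and the target/mean-of-others
ratio is at least 3.0 (strict and inclusive respectively, following the
wording of the derivation rule).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 10 | neighbours in the spatial graph |
| `alpha` | 0.05 | residual Moran level that triggers escalation |
| `cap` | 150 | maximum eigenvectors per fit |
| `schedule` | 0, 1, 5, 10, ... | eigenvector counts tried, in order |
| `threshold` | 0.05 | FDR level for gene calls |
| `max_dist` | 3 mm | sample-to-cortex-ROI distance filter (inclusive) |
| `min_samples` | 300 | expressed-in-at-least filter (strict below) |
| `fpkm_min`, `enr_min` | 2.5, 3.0 | marker-derivation thresholds |

The orientation of the regression — atrophy ranks as response, expression
ranks as predictor — matters once covariates enter (it is symmetric without
them). Atrophy-as-response was chosen because the eigenvectors are meant to
absorb structure in the atrophy field not explained by expression; the
orientation is fixed here and isolated in one internal function should a user
need the transpose.

## What the synthetic data emulates

`simulate_study()` builds the full study object. Its defaults are the
conditions under which the package's operating characteristics are measured:

* **Geometry.** Per donor, samples scatter over a folded two-dimensional
  sheet (80 mm square, ±15 mm folds) embedded in 3-D; inter-sample distances
  are shortest paths over a dense Euclidean neighbour mesh — a standard
  discrete surrogate for surface geodesics. At 200 samples the median
  nearest-neighbour spacing is ≈ 3 mm, comparable to cortical microarray
  sampling. Any externally computed distance matrix can be supplied instead
  (`donor_geometry()`).
* **Expression.** Each gene is a Gaussian-process draw over the geodesic
  distances (squared-exponential, length-scale 25 mm — the centimetre-scale
  regional gradients that dominate cortical expression maps) plus white noise
  (`noise_sd = 1.25`, i.e. non-spatial measurement noise slightly exceeding
  the regional signal, as is typical for microarray probes) plus independent
  per-probe noise. Planted genes instead blend the normal scores of the
  atrophy ranks with the standardised spatial+noise component at the Pearson
  weight $2\sin(\pi\rho/6)$ that yields a marginal Spearman correlation of
  $\rho$ — the injection operates on ranks, so the planted quantity is
  exactly what the pipeline estimates. "Expressed" flags are set where a
  probe exceeds its own 25th percentile, mirroring the binary flags of
  Allen-style bundles.
* **Atrophy.** Volumes are exact radial Gaussian bumps,
  $t(v) = t_{\max} \exp(-\|v - c\|^2 / 2s^2)$, on a 2 mm grid with an
  affine; the three maps share a focus up to a ±6 mm jitter so the same genes
  can associate with all three (the consensus scenario). The *sampled*
  per-sample scores additionally carry a spatially correlated noise field
  (length-scale 10 mm, unit sd) and white sampling error (sd 0.5). This is a
  deliberate modelling choice, not a convenience: VBM t-maps are spatially
  smoothed, so their noise is correlated, and it is precisely this component
  that lets the residual Moran test *see* — and escalate away — smooth
  structure shared with expression. With noiseless atrophy fields the
  response is an exact function of space, no finite eigenvector set makes the
  coefficient test honest, and no stopping rule based on residual
  autocorrelation can rescue it; type-I control under the defaults was
  verified empirically (about 0.06–0.07 at nominal 0.05, versus about 0.4 for
  the unadjusted analysis).

What it does **not** emulate: cortical anatomy (the sheet is synthetic),
Allen normalisation and batch structure (assumed already applied upstream),
inter-donor differences in coverage or hemispheres, probe-sequence
reannotation (consumed as a finished status table), and the registration
chain that puts t-maps into MNI space. Passing tests therefore demonstrate
the statistical machinery under controlled spatial confounding — not that any
particular biological result would replicate.

## Numerical choices

* Voxel lookup rounds half away from zero on each axis (so index 2.5 maps to
  voxel 3 regardless of parity); indices are 0-based, world space is mm. The
  convention at exact half-voxel boundaries is unstated in most map formats;
  this one is fixed and tested.
* Ties at the k-th neighbour distance are broken by smallest index.
* The squared-exponential kernel over geodesic distances need not be positive
  semi-definite (geodesics do not embed in Euclidean space), so GP draws use
  an eigendecomposition square root with negative eigenvalues clipped to
  zero rather than a Cholesky factor.
* BH correction is `stats::p.adjust(method = "BH")` behind the `bh_fdr()`
  surface; the hypergeometric tail is `stats::phyper`. Both are checked in
  the suite against hand-applied step-up arithmetic and exhaustive
  `choose()`-sum enumeration respectively.
* A fit whose residual sum of squares underflows (perfect fit) is treated as
  spatially clean rather than passed to the Moran test.
* Degenerate inputs error early and specifically: constant vectors for
  Moran's I or as the regression predictor, rank-deficient designs (naming
  the eigenvector count), singular affines, out-of-bounds coordinates (naming
  the coordinate), unknown probe mapping statuses, fewer than two donors,
  fewer than two cell types.

## Problem sizes used by the test suite

The operating-characteristic checks run at 6 donors × 200 samples × 500 genes
with 50 planted associations at $|\rho| = 0.6$ (three seeds) for
sensitivity, false-discovery proportion and consensus recovery, and at
1 donor × 200 samples × 200 null genes (three seeds) for type-I control with
and without adjustment. These sizes were chosen to match the per-donor scale
of real cortical bundles while keeping a full run in the order of minutes;
`scripts/acceptance.R` re-runs them from scratch and writes the measured
values as JSON.

## Known limitations

* Moran's I on OLS residuals is mildly biased (the residual projection
  shrinks autocorrelation), so the escalation can stop slightly early; the
  measured type-I of ≈ 0.06–0.07 at nominal 0.05 reflects this. The
  adjusted-residual variants (Cliff–Ord) are a possible refinement.
* Stationarity is assumed; focal autocorrelation confined to a small patch
  may neither trigger escalation nor be absorbed by global eigenvectors.
* The any-probe gene rule maximises sensitivity at the cost of gene-level
  FDR interpretability; probe-level q-values remain the calibrated quantity.
* The sample odds ratio with Haldane correction differs from the
  conditional-MLE estimator near empty cells; p-values are unaffected.
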