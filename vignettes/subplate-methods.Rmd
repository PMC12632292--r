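---
title: "Methods: robust regional growth analysis of the fetal subplate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: robust regional growth analysis of the fetal subplate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subplate)
```

This vignette documents the models and procedures implemented in
**subplate**, the assumptions behind them, the numerical choices that were
genuinely open, and what the synthetic-cohort validation does and does not
show about real fetal MRI data.

## The measurement model

The subplate (SP) is measured on corresponded surface pairs: an outer mesh
sampling the CP/SP boundary and an inner mesh sampling the SP/IZ boundary
with one shared face list, so vertex *i* on both surfaces denotes the same
anatomical location. All coordinates are world millimetres; voxel centers
follow the half-voxel convention (the center of voxel `[i,j,k]` is at
`origin + (index - 0.5) * voxel_size`), stated explicitly to avoid
half-voxel misregistration between mesh and volume metrics.

- **Thickness** is the per-vertex Euclidean distance between corresponding
  vertices — exact under the correspondence assumption, and invariant under
  rigid motion of the pair.
- **Area** is the summed triangle area; with labels, a triangle belongs to
  the majority label of its vertices, ties resolved toward the lowest region
  id, so per-region areas partition the total deterministically.
- **Volume** is voxel count times voxel volume per label.
- **Depth** is the signed displacement of each outer vertex from its
  position on an inflated reference surface, projected on the inflated
  surface normal, then shifted so the per-subject minimum is exactly zero.
  The displacement is kept *signed* before rescaling (the shift absorbs any
  negativity); an absolute-value variant would fold crowns and fundi
  together.
- Regional summaries of vertex fields are **medians**, which tolerate
  boundary vertices and local extraction artifacts better than means.

Two aspects of surface processing have no canonical definition and are
implemented as explicit choices:

- **Inflation** (the reference for depth) is iterative uniform-Laplacian
  smoothing with a per-iteration global rescale restoring the total surface
  area. On an icosphere the equilibrium stays within about 3% of the exact
  sphere because uniform (combinatorial) weights slightly prefer the twelve
  valence-5 vertices; residual harmonic perturbations are damped below 5% of
  their input amplitude at the defaults (100–200 iterations, step 0.5).
  This is accurate enough for a depth *reference*, whose role is to carry
  the smooth, low-frequency component of the surface.
- **Curvature** for the smoothness quality score uses the cotangent-weighted
  mean-curvature normal with one-ring-area normalization — the standard
  discrete operator — because no particular discretization is canonical for
  this purpose.
- The synthetic **voxelizer** labels voxels by radial containment about the
  outer-mesh centroid. This is exact for star-shaped surfaces, which covers
  every fixture the generator produces; it is not a general
  point-in-polyhedron test and is documented as such.

## The robust growth model

All covariate corrections and trajectory fits go through one estimator:
polynomial regression of a measure on gestational age (GA), degree 1 or 2,
fit by RANSAC and selected by AIC.

Fitting proceeds per degree: (1) an initial full-sample least-squares fit
provides a robust residual scale, and the inlier threshold is fixed at
`2.0 x 1.4826 x MAD` of those residuals; (2) 100 minimal vertex sets are
drawn under a fixed seed (default 42), each candidate's consensus set is the
observations within the threshold, and the largest consensus wins (ties by
consensus RSS); (3) the consensus set is refined to a fixed point by
alternating a least-squares refit with re-thresholding; (4) the final
coefficients are the least-squares refit on the stable consensus set. If the
consensus holds fewer than 75% of the sample the fit falls back to
full-sample least squares and is flagged.

Choices worth recording:

- **The threshold is global, not per-trial.** A per-trial MAD lets a
  degenerate trial anchored on outliers inflate its own threshold and win
  the consensus vote; a threshold fixed from the initial fit makes trials
  comparable. With zero noise the threshold collapses to zero, every point
  is a consensus member, and the fit equals ordinary least squares exactly —
  a contract the tests pin.
- **Scale 2.0, not larger.** A 3x threshold would trim almost nothing under
  clean noise (slightly lowering estimator variance), but it fails the
  robustness contract: gross deviates at 5 noise SDs survive a 3x threshold
  computed from a contaminated initial fit. The 2x scale keeps the
  breakdown behavior (slope error under 2% up to ~25% contamination) at the
  cost of ~5% benign trimming.
- **Consensus refinement** removes the dependence of the final inlier set on
  which random trial happened to win — a pure variance reduction with no
  effect on the zero-noise or gross-outlier behavior.
- **Basis centering.** The polynomial basis is centered at the covariate
  mean (about 27 weeks for GA) to decorrelate the linear and quadratic
  terms. Centering at a fixed GA value would be harmless for GA but
  catastrophic for other covariates (for a depth covariate near 2.5 mm, a
  basis centered far outside the data makes `x` and `x^2` nearly collinear).
  Coefficients are reported in the raw basis regardless.
- **AIC on the full sample** from the consensus-refit model,
  `n log(RSS/n) + 2k` with `k = degree + 2`, so both degrees are scored on
  identical data. Ties (both models interpolate, e.g. noiseless data) break
  toward the linear model. A known property of this selector is that under
  an exactly linear truth it prefers the spurious quadratic with probability
  near `P(chi^2_1 > 2) ~ 0.16` regardless of the noise level; this is
  intrinsic to AIC for nested models, and users comparing *shapes* of
  fitted trajectories (e.g. before clustering) should be aware that a
  fraction of truly-linear trajectories will carry small spurious
  curvature, and a fraction of mildly-curved ones will be flattened.
- Flexible alternatives (splines) are deliberately out of scope: with 68
  cross-sectional points per cell and gross outliers, the linear/quadratic
  family plus robust fitting is the stability/flexibility trade-off the
  package commits to.

## Covariate correction and adjusted group means

Measures are corrected sequentially — GA, then residual brain volume
(supratentorial volume minus its GA trend), and for thickness additionally
regional SP depth (itself pre-corrected for GA and residual brain volume) —
each step a robust fit as above. Literal residuals are mean-zero, which
would annihilate the group means the downstream comparisons need, so each
step removes only the *centered* effect (`prediction - mean(prediction)`):
sample means are invariant under every step while the spread shrinks to the
residual spread. Correction is performed per region x hemisphere x metric
cell; the cohort is cross-sectional, so no within-subject longitudinal
structure is modeled.

For the trimester comparison (late 2nd, 22–27 wGA vs early 3rd, >27–32 wGA,
strict boundary at 27.0), group means must not depend on where within its
window each group's subjects happen to sit. The GA step therefore
standardizes each group to a uniform grid over its window: the value added
back is the mean of the fitted GA curve over the grid, making the adjusted
group mean an estimate of the window-averaged trajectory. Two details
matter and are design decisions of this package:

1. **The GA standardization step runs after the other covariate steps** in
   the group-mean path. Residual brain volume and adjusted depth are
   orthogonalized to GA by construction, so the order does not change what
   is being estimated; running GA last means the standardized mean carries
   the *final* residual precision, which is exactly what the confidence
   intervals assume. With GA first, the group-mean estimator retains the
   variance that the later covariates would have explained, and measured CI
   coverage drops from ~93% to ~85%.
2. **CIs use the delta method** on the two group-mean standard errors
   (`sd/sqrt(n)` of the adjusted values), with critical z = 1.96:
   `se^2 = (100/m1)^2 (se2^2 + se1^2 (m2/m1)^2)`. This propagation is
   validated in the tests against a 100,000-draw parametric bootstrap.

Homotopic growth differences are Z-tests on the percent-change difference
with pooled SEs. Asymmetry uses `AI = (R - L) x 100 / (0.5 (R + L))`
(positive rightward, bounded in ±200, undefined when `R + L <= 0`), computed
per subject on adjusted values; one-sample t-tests against zero, paired
homotopic t-tests (Cohen's d = mean difference / SD of differences), and
AI-change Z-tests between trimester groups follow, each corrected by
Benjamini–Hochberg across the 17 regions within a metric (one family per
metric, and per group where applicable). Degenerate inputs (zero or
floating-point-level variance, as arise on noiseless synthetic data) are
flagged and resolved by the documented convention: p = 1 when the effect is
also zero, p = 0 otherwise.

ANCOVA uses effect (sum-to-zero) coding with type-III marginal sums of
squares — each effect's SS is the RSS increase from deleting its columns
from the full model — and partial eta squared
`SS_effect / (SS_effect + SS_error)`. The repeated-measures variant is the
univariate split-plot form: between-subject effects are tested against the
subject stratum, within-subject effects against the residual stratum. A
multivariate or sphericity-corrected approach is not implemented; the
univariate form is labeled as such in the output. Subjects with unknown sex
are dropped from models containing sex terms.

## Trajectories and clustering

Fitted curves are sampled every 0.1 weeks on 22.0–32.0 (101 points) and converted to relative growth rates
`rate_i = 100 (v_{i+1} - v_i) / (0.1 v(22))` at the 100 interval midpoints
(22.05 … 31.95). The baseline is the trajectory start `v(22.0)` — the
alternative local-value normalization would break the identity
`AUC = 100 (v(32) - v(22)) / v(22)`, which the package treats as the
definition of cumulative growth and verifies to 1e-9 relative. Rate curves
are invariant under rescaling of the measure, which is what makes
cross-regional and cross-metric shape comparison meaningful.

Ward linkage (`ward.D2` on Euclidean distances between rate curves — the
squared-increase-of-variance formulation) clusters the
region x hemisphere profiles; both hemispheres enter separately so that the
bilateral symmetry matrix is computable. The cluster count maximizes the
mean silhouette over the candidate range unless overridden (the analog of
dendrogram inspection); identical profiles are a flagged degenerate case
with k forced to 1. Per-cluster metrics on the cluster-averaged rate curve:
peak rate, peak time (ties to the earliest midpoint, which is why peak
times land on x.x5 values), AUC, and growth density — the SD of the rate
curve after a centered moving average of 0.5 weeks (5 samples, truncated at
the edges; no smoother being canonical, this one is pinned in code). The
symmetry matrix cell (i, j) counts region names with the left hemisphere in
cluster i and the right in cluster j, normalized by the number of unique
regions touching either cluster; diagonal cells are the homotopic
consistency of each cluster.

## The synthetic cohort

The generator emulates the statistical structure of a 68-subject
cross-sectional fetal cohort: GA uniform on 22–32 weeks (the real cohort's
GA distribution beyond mean/range is unknown; uniform is a stand-in, not an
inference), sex approximately balanced with a small unknown fraction,
supratentorial brain volume following a monotone quadratic law rising
~4.25-fold over the window with 5% lognormal scatter, and per
region x hemisphere x metric measures

`value = baseline x archetype(GA) x (BV/BV_law)^gamma x (1 ± AI/200) + noise`.

Three archetype shapes per metric (early-peaking decelerating quadratic,
steady linear, late-peaking accelerating quadratic, all normalized to 1 at
22 weeks) are assigned to the 17 regions; their coefficients are calibrated
so the uniform-GA trimester percent changes land at field-typical values
(thickness ~28–49% across archetypes, area ~64%, volume ~65–95%).
Allometric exponents are 1/3 for the linear measures (thickness, depth),
2/3 for area, 1 for volume. The multiplicative hemisphere factor
`(1 ± AI/200)` makes the planted AI exact under the AI formula — the reason
for choosing it. Noise is Gaussian at a 10% coefficient of variation per
metric by default; a configurable fraction (default 5%) of rows is replaced
by gross deviates 5–8 noise SDs out, emulating segmentation failures, which
is the contamination regime the RANSAC fit is built for. Everything is a
deterministic function of the configuration object, and all estimands
(percent change via closed-form uniform-GA means, AI, cluster labels) are
stored as ground truth.

Two honest caveats from the validation runs:

- Gross outliers propagate *unrobustified* into per-subject AI ratios (the
  asymmetry chain has no consensus step), inflating the AI spread from
  ~14 to ~30 percentage points and skewing extreme ratios toward ±200. The
  parameter-recovery validation of percent change and asymmetry is
  therefore run at the 10%-CV noise condition without contamination; with
  the default 5% contamination, asymmetry detection loses power roughly as
  a doubling of the AI standard error.
- At 10% CV noise, trajectory-*shape* recovery on the cohort is limited by
  AIC degree selection: mildly curved archetypes are sometimes fit linear,
  which flattens their rate curve toward the steady archetype, so the
  silhouette-selected k on noisy cohorts can differ from the planted 3. The
  clustering machinery itself recovers well-separated rate-curve archetypes
  (separation 10x noise) with ARI = 1 and the correct k in ≥19/20 seeds,
  degrading monotonically with noise.

What passing these validations does **not** show about real data: the
generator's regional laws are exactly in the model family (no model
misspecification), labels and correspondences are exact (no parcellation or
registration error), noise is Gaussian (no motion artifacts or intensity
bias), and the cohort is cross-sectional with uniform GA. Results on real
fetal MRI inherit none of these guarantees.

## Problem sizes and determinism

Test and validation problem sizes are chosen to exercise the asymptotics
the methods rely on while staying desk-scale: icospheres at subdivision 3–4
(642–2,562 vertices; meshes in production pipelines are typically ~40k
vertices and only change constants), shell voxelization at 25 mm radius and
0.5 mm voxels (~10^5 labeled voxels), cohorts of 68 subjects, 20-seed
repetitions for recovery checks, and 200–1,000 draws for null-calibration
checks. Every stochastic component is seeded: the cohort from its
configuration seed, every robust fit from the fixed RANSAC seed (applied
with save/restore of the caller's RNG state, so library calls never perturb
a user's simulation stream), and the run log records every seed and
decision parameter needed to replay a pipeline run bit-identically.
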