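---
title: "Morphometric complexity biomarkers of lung CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric complexity biomarkers of lung CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungfractal)
```

`lungfractal` quantifies the spatial organization of aerated lung
parenchyma on CT with three scalar biomarkers, compares them before and
after thoracic radiotherapy, and feeds them — together with dose–volume
metrics — into an interpretable model of radiation pneumonitis (RP) risk.
This vignette is the package's own account of the methods: what each
estimator computes, which tunable parameters matter and why their defaults
were chosen, what the synthetic-data generators emulate, and where the
known limitations are.

## The normal attenuation area

All fractal metrics operate on a binary mask, the *normal attenuation
area* (NAA): voxels inside a lung segmentation whose attenuation satisfies
−950 HU < HU ≤ −700 HU. The window separates normally aerated tissue from
emphysema-like hyperlucency (≤ −950 HU) and from consolidation, vessels
and soft tissue (> −700 HU). The boundary semantics are deliberately
asymmetric — lower bound exclusive, upper bound inclusive — and
`make_naa_mask()` applies them literally; a voxel at exactly −950 HU is
excluded, one at exactly −700 HU is included. Lung segmentation itself is
an input, not a product: masks arrive from upstream (typically manual or
semi-automatic segmentation), and the package only intersects them with
the window.

Coordinate conventions: arrays are indexed (x, y, z) with x
fastest-varying; world coordinates in mm are `(index − 1) × spacing`.
Typical diagnostic reconstructions are anisotropic (e.g. 1.0 × 1.0 ×
2.5 mm). The two cube-grid metrics (box counting, lacunarity) assume cubic
cells, so they run on a nearest-neighbour isotropic resampling of the mask
(default 1 mm, `resample_isotropic()`); the MST metric needs only pairwise
distances and therefore uses the physical mm coordinates of the *original*
voxels, avoiding a second interpolation.

## The three estimators

**Box-counting dimension.** `box_counting_dimension()` counts, for each
box edge *s* (voxels), the number N(s) of grid-aligned cubes containing at
least one occupied voxel, and reports the least-squares slope of log N(s)
on log(1/s). Choices that the literature leaves open, fixed here once:

* *Scale schedule*: powers of 2 from 1 voxel up to a quarter of the
  smallest bounding-box dimension, so the coarsest scale still spans ≥ 4
  boxes per axis. Any strictly increasing integer schedule can be passed
  instead (the analytic Menger-sponge check uses {1, 3, 9, 27}).
* *Grid anchor*: the corner of the occupied bounding box, single offset.
  Multi-offset averaging reduces anchor sensitivity but breaks the exact
  analytic counts on aligned phantoms; the anchor is exposed implicitly by
  translating the mask.
* *Fit range*: all scales by default; a sub-range can be selected and the
  fit R² is always reported.

**Lacunarity.** `lacunarity()` glides a cube of edge *r* with stride 1
over every position fully inside the grid and records its occupied mass M.
The per-scale statistic is λ(r) = Var(M)/E(M)² with *population* moments —
the realized mass distribution is the object of interest, not a sample
from a larger one. The reported scalar is the arithmetic mean of λ(r) over
box sizes {2, 4, 8, 16} voxels (truncated to the mask). Two conventions
coexist in the literature; the alternative E(M²)/E(M)² equals λ + 1 and is
bounded below by 1. Published lung values of 0.1–0.2 are only consistent
with the variance-ratio convention used here. λ is not symmetric under
foreground/background complementation (documented, and tested as such),
and within a profile it is computed on the bounding-box crop of the mask
so that empty padding cannot inflate the variance.

**MST fractal dimension.** For a point set of dimension D, the total
length of a Euclidean minimum spanning tree over n uniformly subsampled
points scales as L(n) ∝ n^((D−1)/D). `mst_fractal_dimension()` draws
`reps` random subsets at each size n, averages L(n), fits m = slope of
log L on log n, and reports D = 1/(1 − m). A 1D chain saturates (m ≈ 0,
D ≈ 1), a plane gives m ≈ 1/2, a volume m ≈ 2/3. Subsampling is essential:
a full lung NAA mask has 10⁶–10⁷ voxels, and exact MSTs at that scale are
neither feasible nor necessary since the scaling law holds for subsamples.
Defaults — sizes {256, 512, 1024, 2048, 4096}, 10 repetitions — keep the
largest MST at O(n²) = 1.7·10⁷ distance evaluations (C++ Prim kernel,
total length is unique even when the tree is not). The seed is mandatory
and recorded; fixed seeds give bit-identical estimates. Estimates outside
[0, 3] are *flagged* in the diagnostics, never silently clipped: an
out-of-range value signals a degenerate fit and should be inspected, and a
slope m ≥ 1 (which would put D through infinity) is an error carrying the
raw slope. Masks with fewer than 2 occupied voxels are rejected up front
so no metric ever propagates NaN.

`compute_profile()` bundles the three estimators for a pre/post mask pair
and returns the Δ features (post − pre, exactly); identical inputs give an
exactly zero Δ profile.

## Paired comparison

`wilcoxon_signed_rank()` implements the signed-rank test directly rather
than wrapping an existing routine, because the cohort layer needs an exact
tie-aware branch with a controllable crossover and both sidednesses:

* zero differences are dropped (the classical convention; the count is
  reported), tied absolute differences receive mid-ranks;
* for n ≤ 25 remaining pairs the two-sided p is computed from the full
  null distribution of W⁺ over all 2ⁿ sign assignments, by convolution
  over doubled ranks (identical to enumeration, which is the test oracle);
* above that, a normal approximation with tie-corrected variance and
  continuity correction (cross-checked against `stats::wilcox.test`);
* `alternative = "greater"` tests specifically for a post-treatment
  increase. Published paired-biomarker tables are frequently one-sided in
  this sense: a metric whose differences trend *downward* then prints a
  p-value near 1, whereas a two-sided test would flag the decrease. The
  package defaults to two-sided and exposes the choice; the paired-cohort
  pattern checks in the test suite use "greater" because that is the form
  under which the reference pattern (lacunarity increase significant,
  BoxFD/MSTFD declines with p ≈ 1) is internally consistent.

`compare_pre_post()` assembles the per-metric report: median (IQR) pre,
post and difference (type-7 linearly interpolated percentiles) plus the
signed-rank p per group. The three biomarkers are reported with raw
p-values, without multiplicity correction, matching how such tables are
conventionally presented. `summarize_cohort()` renders event rates and
categorical percentages with exact arithmetic; the rounding convention is
switchable (half-up default, half-down, truncate) because published tables
are not consistent about the half-way case.

## Risk modeling

`rank_features()` trains one random forest (500 trees, √p features per
split, unlimited depth — all config-exposed) per stratified
cross-validation fold and averages the mean decrease in Gini impurity;
the dispersion across folds is reported so that an "important" feature
whose rank is fold-dependent is visible as such. `fit_pruned_tree()` grows
a Gini tree on the selected (top-3 by default) features and prunes by
cost-complexity with the penalty chosen by cross-validated error under the
one-standard-error rule; branches present before but not after pruning are
recorded by feature, making "this predictor was grown then pruned away"
an explicit, inspectable event. Missing feature values are rejected, not
imputed. A single-class table yields a constant-leaf tree rather than an
error.

`evaluate_model()` offers two schemes because single reported metrics in
the applied literature are ambiguous between them: `"holdout"` scores a
fitted tree on an external table, while `"cv-pooled"` (default) refits the
tree recipe per stratified fold and pools out-of-fold leaf probabilities,
so every patient is scored by a tree that never saw them. Accuracy, F1
(positive class = the clinical event, RP grade ≥ 2) and the confusion
matrix use the 0.5 probability cut; AUROC uses the tie-corrected rank
statistic on leaf probabilities (undefined and flagged when a class is
absent); and accuracy is tested against the no-information rate (majority
class frequency) with a one-sided exact binomial tail. Δ features are
accepted as predictors because longitudinal designs use them; note the
temporal caveat — a Δ feature requires the follow-up scan, so models using
it stratify risk at follow-up time, not at treatment planning.

## Synthetic data: what it does and does not emulate

The generators define the verification conditions for every stage:

* `generate_phantom()` — sets with known answers: Menger sponges
  (dimension log 20/log 3, exact box counts by construction), filled
  cubes, slabs, axis-aligned lines, uniform point processes, and
  thresholded Gaussian fields (FFT-smoothed white noise thresholded at the
  exact occupancy quantile) as the lung-texture stand-in.
* `generate_paired_volumes()` — mask-level pre/post pairs with a planted
  lacunarity change at fixed occupancy, by mixing the pre field with an
  independent coarser field and re-thresholding at the same count. The
  contract (requested sign of Δlacunarity; |ΔBoxFD| within tolerance,
  default 0.05) is verified with the package's own estimators and enforced
  by bounded retries. Coarsening at fixed occupancy leaves BoxFD *nearly*
  unchanged, but not exactly: across many pairs the residual ΔBoxFD has a
  small systematic component (≈ +0.002), so mask coarsening realizes a
  per-pair tolerance, not a cohort-level null.
* `generate_paired_cohort()` — measured-profile-level paired tables for
  cohort statistics. Defaults plant the reference change pattern at
  chemoradiotherapy scale: lacunarity +0.016, BoxFD −0.024, MSTFD −0.015,
  with within-patient difference SDs (0.059, 0.034, 0.035) recovered from
  the corresponding published IQR widths (÷1.349 under normality). Setting
  a shift to 0 gives an exact paired null, which is what type-I-error
  checks require and what mask-level generation cannot deliver.
* `generate_cohort()` — feature tables with labels from a planted decision
  list (`feature > threshold` rules in order, branch probabilities,
  optional label noise), features uniform over ranges bracketing published
  clinical values (e.g. V20 0.4–21.4% for an RT-alone-like cohort) so
  planted thresholds are always interior. With 0/1 probabilities and zero
  noise the table is perfectly separable and the downstream tree must
  recover it exactly.

What passing these checks shows: the estimators are mathematically
correct, calibrated, and the pipeline recovers structure it is pointed at.
What it does not show: performance on real lungs. The phantoms match the
published biomarker *ranges*, not the spatial texture of real NAA masks
(no airways, vessels, gravity gradient, scanner noise, or reconstruction
kernel effects), and no claim about patient-level predictive accuracy is
made or testable without clinical data.

## Numerical and degenerate-input policy

Estimator preconditions are enforced as descriptive errors rather than NaN
propagation: empty masks (all metrics), fewer than 3 usable scales or
subsample sizes, subsample sizes exceeding the occupied count, zero mean
gliding-box mass, coincident point sets, and all-zero difference vectors
(which return the degenerate p = 1 with a flag instead of erroring).
Determinism is a contract: every stochastic operation takes a mandatory
seed, derives sub-seeds for internal stages, restores the caller's RNG
state, and repeated runs are byte-identical — tested by serialization.

Problem sizes in the test and acceptance suites (64³–81³ phantoms, MST
subsamples to 4096, 166-patient cohorts, 20–50 replicate batches, 1000–
2000-replicate calibration loops) were chosen as the smallest at which the
asymptotic behaviors under test are comfortably visible: MST scaling-law
recovery at n = 4096 reaches D = 2.9 of the theoretical 3 (the residual is
finite-size bias of the scaling law, not estimator error), and smaller
batches would leave recovery-rate assertions dominated by binomial noise.

## Known limitations

* Pre/post scans are compared as global scalars; no spatial registration
  is attempted (the metrics are translation-invariant, so registration is
  unnecessary for them, but regional analyses would need it).
* The DICOM reader is intentionally minimal: uncompressed explicit-VR
  little-endian single-frame CT series only; anything else errors with the
  reason. NIfTI is the recommended interchange format.
* The box-counting grid uses a single anchor; anchor-averaged variants
  would smooth N(s) on non-aligned structures at the cost of exactness on
  aligned ones.
* The lacunarity scale set {2, 4, 8, 16} and the MST subsample schedule
  are conventions; absolute biomarker values are comparable only between
  profiles computed with identical settings (which is why every profile
  records its settings and seed in the diagnostics).
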