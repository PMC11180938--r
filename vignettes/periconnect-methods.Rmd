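---
title: "Mapping WMH-connected cortex: models, parameters and design choices"
author: "periconnect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping WMH-connected cortex: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periconnect)
```

## The scientific question

White matter hyperintensities (WMH) sit inside fiber bundles. If a bundle
passing through a lesion terminates in a patch of cortex, that patch —
the *WMH-connected cortex* — is the place to look for remote effects of the
lesion: cortical thinning, synaptic density loss (SV2A PET), altered
amyloid/tau uptake. The package operationalizes "connected" with
probabilistic tractography from lesion seeds to the white/gray matter
boundary, and quantifies abnormality with connected/unconnected ratios of
surface metrics. This vignette documents the models, every tunable
parameter, and the decisions made where the design was genuinely open.

## WMH parcellation

Lesion voxels are split into periventricular (pWMH) and deep (dWMH) at a
**10 mm** Euclidean distance from the ventricles, then intersected with the
four lobar white-matter labels, giving eight parcels. Distances come from an
exact distance transform (Felzenszwalb–Huttenlocher lower-envelope
algorithm, run per axis with that axis' voxel size, so anisotropic grids are
handled exactly); distances are voxel-center to voxel-center, measured from
the ventricular *surface* voxels with no prior dilation.

**Tie handling.** A voxel at exactly 10 mm counts as deep ("within 10 mm"
is read as a strict inequality). The threshold is a parameter
(`threshold_mm`), so the opposite convention is one argument away. Raising
the threshold can only move voxels from dWMH to pWMH (tested as a
monotonicity property).

Lesion voxels with no lobar label are excluded from the eight parcels but
retained in the depth and grand totals, since a lobar projection need not
cover all of white matter.

## Probabilistic tracking

The tracker consumes an orientation field: a unit principal direction plus
an angular dispersion (degrees) per white-matter voxel. Fitting such a field
from diffusion data is upstream of this package; the phantom supplies it
directly.

Per seed voxel, `samples_per_voxel` (default **5000**) streamlines start at
uniformly jittered positions inside the voxel. Each step draws a direction
from the local principal direction — sign-flipped if needed to stay within
90° of the previous step — perturbed by a tangential Gaussian with SD equal
to the local dispersion (a small-angle von Mises–Fisher surrogate), then
advances `step_mm`. A streamline succeeds on first entry into a boundary
voxel (that voxel's count increments) and fails on leaving the brain mask,
exceeding `max_steps`, or turning more than `curvature_threshold_deg` in
one step. Defaults: step = 0.5 × smallest voxel dimension, 2000 steps, 80°
— the common defaults of widely used probabilistic trackers. The emitted
total is exact (`5000 × seed voxels`), and emitted = successes + failures
is asserted in tests.

**Reproducibility.** Each seed voxel owns an RNG substream keyed by (master
seed, voxel index) — a splitmix64-seeded Mersenne Twister with an explicit
Box–Muller transform, so results are identical across platforms and
independent of execution order. A corollary tested as a property: adding
seed voxels never decreases any boundary count.

## ROI levels

The low-probability ROI keeps boundary voxels with
`count ≥ 3.08e-7 × total`. Medium and high ROIs are defined by raising the
*count threshold* over the sorted distinct counts until the surface size
first drops to ≤ 50% and ≤ 25% of the low-level size; since size is
non-increasing in the threshold, the result is the **largest** ROI under
each bound, and the three levels are nested. Surface size is the boundary
voxel count (the phantom has no mesh; a spacing-weighted area would slot in
here). A degenerate count distribution that jumps straight past the target
returns the first crossing with a warning.

An alternative reading of the adaptive levels — increasing the *number of
samples* rather than the threshold — cannot shrink an ROI under a fixed
relative threshold, so the threshold search is implemented; the acceptance
surface (the 50%/25% size criterion) is identical either way. Whether the
low-level cut is `≥` or `>` is likewise a configuration flag (`strict`),
with `≥` the default.

The reference ROI at each level is the within-region complement of the
*full* ROI (not of the regional ROI): unconnected cortex is everything the
lesion does not reach, split by region for reporting.

## Metrics and ratios

Thickness is consumed as given (mm at boundary voxels). PET metrics are
converted to SUVR by dividing by the mean uptake over the cerebellar
reference mask, then smoothed **on the boundary adjacency graph** with an
iterated conservative diffusion: every 26-neighbor edge exchanges 1/27 of
the value difference per iteration, which conserves total mass exactly
(antisymmetric pairwise exchange) and keeps values positive. The iteration
count is calibrated from the kernel's second moment on an ideal flat
8-neighbor sheet — per-axis variance `6 s² / 27` per iteration for voxel
size `s` — so that `2.355 σ` matches the requested FWHM (default **5 mm**;
measured impulse-response FWHM on a flat sheet is 4.96 mm). Requests below
the voxel size return the identity with a warning. Thickness is *not*
smoothed, mirroring the convention that only PET surface maps are.

Regional ratios are means of means:
`ratio_r = mean(metric | ROI_r) / mean(metric | rROI_r)`, computed only
when both masks hold at least `min_voxels` (default **10**) voxels — small
ROIs make the numerator mean unstable, and real analyses show
region-dependent availability. The averaged ratio is the unweighted mean of
the ratios present; absent regions are dropped, not imputed as 1.0 (a
region with no connected cortex carries no information about connected
cortex). Ratios are invariant under metric rescaling, which is why SUVR
reference choice cancels out of them.

Longitudinal ratios reuse the **baseline** ROI set with the month-12
metric, so change is measured over a fixed footprint.

## Statistics

* **One-sample vs 1**: Shapiro–Wilk gate at p < 0.05 per family; normal →
  one-sample t, otherwise Wilcoxon signed-rank against 1. (The rank-based
  two-sample test sometimes named in this context does not apply to a
  one-sample design; the signed-rank test is its one-sample analogue.)
  Zero-variance inputs are flagged degenerate rather than producing a
  statistic.
* **Groups**: ANOVA when residuals pass the same gate, else
  Kruskal–Wallis; pairwise contrasts as mean difference ± Welch SE with
  uncorrected p, matching the reporting convention for these comparisons.
* **Regression**: OLS of cognition on the ratio with age, education and WMH
  volume as covariates; collinear designs are flagged, not reported.
* **BH correction**: `stats::p.adjust(method = "BH")` behind `bh_adjust()`;
  the test suite checks it against an independent hand-rolled step-up
  implementation. The default family is one analysis × connectivity level;
  the grouping is a parameter because the family definition is a genuine
  modeling choice.
* **Longitudinal**: with exactly two timepoints and complete pairs,
  repeated-measures ANOVA on time reduces algebraically to the paired t
  test (F = t², asserted numerically against a generic repeated-measures
  decomposition), and the measure × time interaction of a random-intercept
  mixed model reduces to a paired contrast on per-subject standardized
  changes `d_i = Δz_ratio − Δz_MMSE`. Both measures are standardized by
  their *baseline* mean and SD, anchoring follow-up values to the baseline
  scale. Negative mean `d` means the ratio declines faster than cognition.
  A general mixed-model solver would add machinery without changing a
  single number here, so it is deliberately absent; more than two
  timepoints is out of scope.
* All tests are two-tailed at α = 0.05.

## The phantom

The phantom is the package's test bed: a concentric "brain" on a 64³ grid
at 2 mm isotropic (desk-scale, distances still meaningful in mm) —
central ventricle ball (radius 0.155 L, with L the half-extent), white
matter shell, a 2-voxel gray-matter ribbon, and a detached cerebellar
reference ball below the cerebrum. The WM/GM boundary is defined
morphologically (WM voxels 26-adjacent to the ribbon), exactly as the
analysis consumes it. Six cortical sectors carry the standard region names
(cingulate as a para-midline band, insula as lateral caps, the four lobes
as quadrants); any six-way partition would serve, since the real lobar
atlas is upstream of the package.

The orientation field is radial (ventricle → cortex), so every white-matter
voxel lies on a path from deep white matter to the overlying boundary, with
a default dispersion of 10° to exercise the probabilistic machinery.
Lesions are placed at deterministic positions per (lobe, depth, radius)
request — deep centers midway through the admissible radial band, for a
minimum ventricular distance comfortably ≥ 10 mm, periventricular centers
3.5 mm clear of the ventricle — and every placement is re-verified against
the distance transform, with an explicit error when a grid cannot satisfy a
request (e.g. deep WM does not exist on very small grids).

**Ground truth.** The true connected patch per lesion is the lesion's
radial footprint on the boundary: rays cast from a 9×9×9 sub-grid of every
lesion voxel, followed through the orientation field voxel-wise with the
same stepping rule as the tracker at zero dispersion. Nine offsets per axis
is past the point where the hit set stops growing, so the footprint is the
deterministic continuum limit of the tracker over the lesion volume — which
is exactly what "the cortex radially overlying the lesion" should mean on
this geometry. On the default phantom with dispersion 0 the tracked
low-level ROI matches this truth at Dice ≈ 0.96; residual disagreement is
single rim voxels whose preimage in the seed cube is a sliver either missed
by 5000 random jitters or thinner than the ray grid.

Metrics are planted as regional baseline × effect × multiplicative
lognormal noise (`sdlog = sqrt(log(1 + f²))` for noise fraction `f`),
with the effect applied inside the truth patch. Lognormal noise keeps
thickness and uptake positive. With zero noise every planted ratio is
recovered *exactly* by construction; with the default 5% noise the averaged
ratio is recovered to well under 0.01 mean absolute error over 100
replicates (tested). Defaults plant a 0.95 thickness ratio and 0.92 SV2A
ratio, matching the magnitude of reported connected-cortex effects, with
amyloid/tau planted mildly above 1.

**Cohorts.** `make_cohort()` draws 59/27/21 AD/MCI/CN subjects (CDR 1 /
0.5 / 0), group-specific ages (70.7 ± 8.0, 71.1 ± 7.0, 70.0 ± 8.0 years),
education 10.7 ± 4.5 years, lognormal WMH volumes, per-subject ratios
around group means (SD 0.035), and a cognitive score from a linear model
with ratio coefficient −37.8 and residual SD 5, so covariate-adjusted
regression can be validated against a known coefficient.
`make_longitudinal_cohort()` emulates the 23-subject follow-up sample:
baseline ratio 0.976 ± 0.034 with a planted −0.033 annual change (SD 0.02),
baseline MMSE 21.4 ± 5.1 with a −1.8 change (SD 3.0; the change SDs are not
reported anywhere, so these are fixed package choices). The distribution of
WMH volumes and lesion counts per subject is configurable and makes no
claim of realism.

**What the phantom does not emulate** — and therefore what passing tests do
not show about real data: MRI contrast and bias fields, crossing fibers and
orientation-fitting error, partial-volume effects in PET, mesh-based
surface geometry, hemispheric asymmetry, registration error. The phantom
validates the *pipeline arithmetic* (distances, counting, thresholds,
ratios, statistics), not the upstream measurement chain.

## Numerical choices and degenerate inputs

* Voxel indexing is 0-based in world terms: voxel `(i,j,k)` (0-based) has
  center `(i,j,k) × spacing` mm; the NIfTI affine is `diag(spacing)` with
  origin at voxel 0. All distances, steps and FWHM are in mm.
* Seeds: master seed → per-subject (`seed + 7919 i`) → follow-up
  (`seed + 1`) → per-seed-voxel tracker substreams. Identical config + seed
  is bit-reproducible end to end (tested at the pipeline level).
* Empty seed masks, empty ventricle masks, fields undefined at seeds,
  non-positive reference means, zero baseline SDs and grid mismatches all
  raise named errors at the stage that detects them.
* Problem sizes used by the validation suite: 64³ default phantoms; 100
  replicates for ratio recovery; 10 000 replicates for the type-I-error
  calibration of the one-sample test (empirical rate within [0.03, 0.07]);
  500 replicates for the longitudinal power checks; 50 random ≤ 32³ grids
  for the distance-transform oracle. These sizes make the full suite run in
  a couple of minutes on a single CPU while keeping every Monte-Carlo
  tolerance comfortably wide of its threshold.

## Known limitations

* One compartment: no hemispheres, no mesh, no gyri; "surface size" is a
  voxel count.
* The tracker is a minimal single-fiber probabilistic model — no crossing
  fibers, no anatomical exclusion masks, no distortion handling.
* The longitudinal layer is specialized to two timepoints by design.
* Smoothing is graph-based, not geodesic; on a strongly curved boundary the
  effective kernel is slightly anisotropic (the FWHM calibration assumes a
  locally flat sheet and is verified to 20% on one).
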