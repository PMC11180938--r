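# periconnect

White matter hyperintensities (WMH) — the bright lesions seen on T2/FLAIR
MRI in small vessel disease and Alzheimer's disease — do not only damage the
white matter they occupy. Through the fiber bundles passing through them
they are coupled to remote cortex, and that *WMH-connected* cortex shows
thinning, synaptic loss and altered tracer uptake relative to cortex with no
connection to any lesion. `periconnect` implements the full analysis chain
for quantifying this remote effect, for imaging researchers who have
lesion masks, a fiber orientation field and surface metric maps and want
lesion-connected cortical readouts with defensible statistics.

## What it computes

1. **WMH parcellation.** Lesion voxels are classified as periventricular
   (pWMH) or deep (dWMH) by a 10 mm Euclidean distance threshold from the
   ventricles (exact anisotropic distance transform), then split by the four
   lobar white-matter labels into eight parcels.
2. **Connectivity mapping.** Probabilistic streamlines are seeded in each
   WMH parcel (5000 per seed voxel) and propagated through the per-voxel
   orientation field until they enter the white/gray matter boundary. The
   termination counts, normalized by the emitted total `N`, give the
   probability that a boundary voxel is connected to the lesion.
3. **Three nested ROIs.** The low-probability ROI keeps boundary voxels with
   `count >= 3.08e-7 * N`. Medium and high ROIs are found by raising the
   count threshold until the surface size first drops to 50% and 25% of the
   low-level surface size. Cortex outside the ROI is the reference (rROI).
4. **Ratios.** For each metric map (cortical thickness; amyloid, tau and
   SV2A SUVR referenced to cerebellar cortex, smoothed on the boundary
   graph at 5 mm FWHM) and each of six cortical regions — frontal, temporal,
   parietal, occipital, cingulate, insula —

   `ratio_r = mean(metric | ROI_r) / mean(metric | rROI_r)`,

   with the averaged ratio the unweighted mean over regions. Values below 1
   mean the connected cortex is worse off.
5. **Statistics.** One-sample tests of ratios against 1 with Shapiro–Wilk
   normality gating (t test or signed-rank), ANOVA/Kruskal–Wallis group
   comparisons with pairwise mean differences ± SE, OLS regressions of
   cognition on ratios adjusted for age, education and WMH volume,
   Benjamini–Hochberg correction, and a longitudinal layer: paired
   two-timepoint change tests (the two-timepoint reduction of
   repeated-measures ANOVA, F = t²) and a baseline-anchored standardized
   comparison of the ratio's decline against the MMSE's.

Because cohort data of this kind are not public, the package ships a
synthetic brain phantom (`make_phantom()`, `make_cohort()`,
`make_followup()`) with planted ground truth — lesion locations, the true
connected cortical patch, planted ratio effects, regression coefficients
and 12-month changes — so every stage can be validated against known truth.

## Worked example

```r
library(periconnect)

cfg <- phantom_config(seed = 42)          # 64^3 grid, 2 mm, two lesions
ph  <- make_phantom(cfg)
boundary <- ph$tissue == tissue_codes()[["wm_gm_boundary"]]

parc <- parcellate_wmh(ph$wmh, ph$tissue == tissue_codes()[["ventricle"]],
                       ph$lobar_wm, ph$spacing_mm)
subset(parc$volumes_ml, n_voxels > 0)
#>           parcel n_voxels volume_ml
#> 2  pWMH_parietal       24     0.192
#> 5   dWMH_frontal       31     0.248
#> 6  dWMH_parietal        6     0.048
#> 9          total       61     0.488
#> 10          pWMH       24     0.192
#> 11          dWMH       37     0.296

cm   <- track_streamlines(parc$totals$dWMH, ph$field, boundary, ph$brain,
                          ph$spacing_mm, tracking_params(seed = 42))
rois <- threshold_roi_set(cm, boundary)
sapply(rois$levels, function(l) l$size)
#>    low medium   high
#>    197     98     49

m  <- surface_metric(ph$metrics$thickness, boundary, "thickness", "mm",
                     spacing_mm = ph$spacing_mm)
rr <- regional_ratios(m, rois, ph$regions, subject = "sub-001", parcel = "dWMH")
rr[, c("parcel", "level", "frontal", "average", "n_regions")]
#>   parcel  level   frontal   average n_regions
#> 1   dWMH    low 0.9680255 0.9579925         2
#> 2   dWMH medium 0.9577200 0.9544130         2
#> 3   dWMH   high 0.9509748 0.9575034         2
```

The deep-lesion seed reaches 197 boundary voxels at the low level; the
adaptive search shrinks that to 98 (49.7%) and 49 (24.9%). The thickness in
the connected cortex is ~4–5% lower than in the unconnected cortex of the
same regions, recovering the 5% planted effect; ratios are reported only
for the two regions overlying the lesions (`n_regions = 2`), since the
other regions hold no connected cortex.

A thin CLI wraps the same functions
(`inst/cli/periconnect simulate|parcellate|track|run`), and
`run_pipeline(run_config(...))` executes parcellation → tracking → ROI
definition → ratios in one call, writing NIfTI volumes, tidy CSV tables and
a manifest with input hashes and the seed.

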