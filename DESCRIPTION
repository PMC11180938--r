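Package: periconnect
Title: Lesion-Connected Cortex Mapping for White Matter Hyperintensities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps the cortex connected to white matter hyperintensities (WMH)
    with probabilistic streamline tractography and quantifies cortical
    abnormality in the connected cortex. WMH masks are parcellated into
    periventricular and deep classes by a 10 mm ventricular distance
    threshold and split by lobe; streamlines seeded in each WMH parcel are
    propagated through a voxel orientation field to the white/gray matter
    boundary, and the resulting connectivity-probability map is thresholded
    at a fixed low level plus adaptive medium and high levels (50% and 25%
    of the low-level surface size). Connected/unconnected ratios of cortical
    thickness and reference-normalized PET uptake (SUVR) are computed over
    six cortical regions, and the accompanying statistics layer provides
    one-sample tests of ratios against unity with normality gating, group
    comparisons, covariate-adjusted regressions with Benjamini-Hochberg
    correction, and baseline-anchored longitudinal slope comparisons. A
    synthetic brain phantom with planted ground truth supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
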