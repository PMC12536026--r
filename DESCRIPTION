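Package: glymphr
Title: Glymphatic MRI Biomarkers for ALS Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for resting-state MRI markers of glymphatic
    function in amyotrophic lateral sclerosis (ALS) case-control cohorts.
    Computes the lagged cross-correlation coupling between the global
    gray-matter BOLD signal and the CSF inflow signal (with a
    subject-reassignment permutation null), the DTI-ALPS perivascular
    diffusivity index, and the choroid plexus volume fraction; provides
    normality-gated group comparisons, FDR-corrected correlation matrices,
    partial correlation, and intraclass correlation; and fits per-marker ROC
    curves and a combined logistic nomogram with bootstrap-corrected
    calibration and decision-curve analysis. A seeded synthetic cohort
    generator emulates the marker distributions and derivative-coupled
    signal pairs the analysis assumes, so the full pipeline runs without
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    pROC,
    signal,
    stats,
    utils
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
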