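Package: EmphyDose
Title: Emphysema-Excluded Dose-Volume Metrics and Radiation Pneumonitis Risk Models
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies emphysematous lung (low attenuation volume, LAV) on CT by
    Hounsfield-unit thresholding, computes traditional and LAV-excluded dose-volume
    parameters (Vx, Vx-LAVx, ratios, MLD, MED, MLWED) from a radiotherapy dose grid
    resampled onto the CT geometry, and compares the ability of each parameter to
    predict symptomatic radiation pneumonitis using standardized, covariate-adjusted
    logistic models scored by AUC, AIC, BIC, integrated discrimination improvement
    and continuous net reclassification improvement. Includes readers for DICOM CT
    series, RT Dose and RT Structure Set objects, NIfTI fixture I/O, and a synthetic
    phantom-cohort generator that emulates the summary statistics of a thoracic
    radiotherapy cohort for desk-scale validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
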