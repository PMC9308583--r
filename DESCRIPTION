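Package: myelinpet
Title: Kinetic Quantification of Dynamic Myelin PET with Arterial Input
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying dynamic brain PET scans of myelin-binding
    tracers with arterial blood sampling. Builds metabolite-corrected arterial
    plasma input functions (continuous detector calibration, Hill parent
    fraction model, plasma-to-whole-blood ratios), fits one- and two-tissue
    compartment models with fractional blood volume by weighted nonlinear
    least squares (macroparameters, percent standard errors, AIC), provides
    the linearized estimators Patlak, Logan, MLAIR1 and MLAIR2 plus
    standardized uptake values, and implements study-level procedures:
    reliability filtering, AIC model-preference tables, method-comparison
    regressions, grey/white-matter statistics, and MRI-based classification
    of multiple sclerosis lesions by expected myelin density. A synthetic
    cohort generator reproduces the statistical structure these analyses
    assume so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    car,
    nortest,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
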