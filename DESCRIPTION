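Package: icushift
Title: External Validity, Fairness, and Dataset-Shift Audits for ICU Mortality Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing how ICU in-hospital mortality risk models
    transfer across care environments. Fits l2-penalized logistic models per
    hospital or region under a fixed-sample-size resampling protocol, computes
    discrimination (AUC), calibration slope, false-negative-rate and
    calibration-slope disparities between racial groups, and their
    generalization gaps; tests for dataset shift between environments with an
    unbiased kernel maximum mean discrepancy permutation test; and attributes
    shifts to specific variables by pooling environments with context
    indicators and running the Fast Causal Inference algorithm. A synthetic
    multi-hospital cohort generator with a known ground-truth causal graph
    supports end-to-end validation without access to credentialed data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    glmnet,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
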