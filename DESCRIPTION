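Package: bsdrisk
Title: Prognostic Modelling and Risk Calculation for Bipolar-Spectrum Disorder Onset
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates lasso-Cox prognostic models for the onset of
    bipolar-spectrum disorder (BSD) in right-censored adolescent cohorts.
    Provides a cohort data model with explicit missingness and
    patient/caregiver rating integration, a synthetic-cohort generator with
    known ground truth, Kaplan-Meier and univariate Cox screening,
    L1-penalized Gaussian/binomial/Cox regression with regularization paths,
    lasso-based multiple imputation nested inside leave-one-out
    cross-validation and bootstrap out-of-bag validation, time-resolved
    cumulative/dynamic AUC with bootstrap confidence bands, AIC-based risk
    stratification with stratified survival curves, and the published
    four-item BSD risk calculator with a 20-month probability mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
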