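Package: bcgco
Title: Cardiac Output Estimation from Carotid and Abdominal
    Ballistocardiography
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Estimates cardiac output (CO, L/min) from skin-surface
    ballistocardiography (BCG) recorded over the carotid artery and the
    abdominal aorta, together with a simultaneous ECG. The pipeline
    band-pass filters the raw channels, detects QRS complexes with the
    Hamilton-Tompkins algorithm, isolates the beat-locked circulatory
    component of each BCG channel with a QRS-referenced recursive
    least-squares adaptive filter, computes 66 morphological features on
    overlapping 10-s analysis windows, selects features with an
    mRMR-seeded Plus-l Take-Away-r wrapper under subject-wise
    cross-validation, and fits a multiple linear regression of CO on the
    standardized features. Includes the published fixed-coefficient
    regression model, a Bland-Altman / percentage-error agreement suite,
    and a seeded cardio-mechanical signal simulator that provides ground
    truth for every processing stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
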