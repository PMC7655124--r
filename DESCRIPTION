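Package: hippofeat
Title: High-Frequency iEEG Features for Characterizing the Epileptic Hippocampus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature pipeline for interictal intracranial EEG of the human
    hippocampus. Detects high-frequency oscillations (ripples 80-250 Hz, fast
    ripples 250-600 Hz) with a multi-band Hilbert-envelope detector, detects
    interictal epileptiform discharges with a Barkmeier-style amplitude/slope
    detector, estimates high-frequency functional connectivity (linear
    correlation and relative entropy) between adjacent contacts, aggregates
    per-channel feature vectors across rest and cognitive-task conditions, runs
    the associated statistical battery (paired t, Mann-Whitney, ROC with
    Hanley-McNeil inference), and classifies epileptic versus non-epileptic
    hippocampus with a PCA + SVM model under leave-one-hippocampus-out
    cross-validation. Includes a synthetic iEEG cohort generator with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
SystemRequirements: FFTW3 (libfftw3)
LinkingTo:
    Rcpp
Config/testthat/edition: 3
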