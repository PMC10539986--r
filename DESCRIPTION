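Package: eegresponse
Title: Resting-State EEG Features and Nested Cross-Validated kNN for
    Antidepressant Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to predict antidepressant treatment response from
    resting-state eyes-closed electroencephalography (EEG). Implements
    Welch relative band power and multiscale sample entropy feature
    extraction on 32-channel recordings, reduction to a 152-dimensional
    region and hemispheric-asymmetry feature vector, k-nearest-neighbour
    classification under fully nested leave-one-out and k-fold
    cross-validation, external-cohort prediction, permutation feature
    importance, and confidence-interval reporting for the resulting
    metrics. A synthetic EEG cohort generator with controllable
    class-conditional asymmetry and complexity effects makes every stage
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
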