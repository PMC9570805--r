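Package: sladl
Title: Classification of Wheelchair-Related Shoulder-Loading Activities
    from Wearable Sensor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for per-sample classification of eight
    wheelchair-related shoulder-loading activities of daily living from
    multi-site wearable sensor recordings (five inertial measurement units
    plus two surface electromyography channels). Provides a synthetic cohort
    generator emulating the laboratory sensor setup, signal preprocessing
    (moving-average downsampling of inertial channels, zero-phase Butterworth
    electromyography envelope extraction), a recurrent sequence classifier
    (gated recurrent unit followed by a bidirectional long short-term memory
    layer) trained with leave-one-subject-out cross-validation and
    validation-accuracy early stopping, sensor-combination ablation, and
    per-class confusion-chart performance measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
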