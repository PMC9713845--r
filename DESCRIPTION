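Package: dailyadhere
Title: Personalized Daily Adherence Prediction for Gamified Cognitive Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting whether a participant in a mobile cognitive
    training program will meet a minimal daily adherence criterion (at least
    ten minutes of play) on the next day, given their recent gameplay history.
    Implements per-participant window-size estimation from the dominant
    spectral component of the play-time series, sliding-window supervised
    framing with a strict train/test day split, transform-based time-series
    augmentation (jittering, scaling, cubic-spline time warping and their
    stacked combinations), small per-participant 1-D convolutional, LSTM and
    hybrid CNN-LSTM classifiers trained by backpropagation with Adam, a
    five-metric evaluation harness (precision, recall, F1, rank-based AUC,
    accuracy) with macro-averaging across the cohort, and a seeded synthetic
    cohort generator that emulates the weekly play structure of such studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
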