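Package: liftrisk
Title: Lifting-Risk Classification from Wearable IMU Signals with Small-Data Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying the back-injury risk of
    manual lifting trials recorded by six body-worn inertial measurement
    units (tri-axial accelerometer and gyroscope, 25 Hz). Provides a
    synthetic lifting-trial simulator with class-dependent acceleration
    bursts, Butterworth band-pass preprocessing, an image-style encoding of
    multi-channel time series, a compact average-pooling VGG-style
    convolutional network (with max-pooling, simple-CNN, MLP and
    convolutional-LSTM comparison models) trained with ADAM and early
    stopping, per-zone stratified Monte-Carlo cross-validation, confusion
    matrix statistics including the Gorodkin multiclass R_K correlation,
    and gradient saliency mapping of trained models. The neural-network
    engine (im2col convolutions, pooling, batch normalisation, dropout,
    LSTM, softmax cross-entropy, ADAM) is implemented in the package with
    'RcppArmadillo'.
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
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
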