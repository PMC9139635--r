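Package: busnext
Title: Quality-Gated Malignancy Scoring of Breast Ultrasound Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts breast tumor malignancy from B-mode ultrasound frame
    sequences. A from-scratch ConvNeXt convolutional classifier scores each
    frame, per-frame image quality is assessed with a brightness estimate and
    a variance-of-Laplacian blurriness metric, and the per-frame scores are
    fused into a sequence-level malignancy score by quality-gated pooling.
    Includes Grad-CAM visual explanations, standard classification metrics
    with ROC/AUC, a seeded synthetic speckle-phantom generator for
    benign/malignant test sequences, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
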