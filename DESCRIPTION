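Package: bcgaf
Title: Atrial Fibrillation Detection from Ballistocardiogram Signals by
    Multi-Scale Feature Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects atrial fibrillation (AF) in single-channel
    ballistocardiogram (BCG) recordings by fusing two feature scales: a 1-D
    beat-morphology feature learned by a bidirectional LSTM from 1-s heartbeat
    segments, and a 2-D rhythm feature obtained by phase-space reconstruction
    (Takens delay embedding with autocorrelation delay and false-nearest-
    neighbour dimension selection) of 24-s segments, projected onto the plane
    orthogonal to the main diagonal. The two features are combined by a
    convolutional network whose fusion layer can be gated by self-attention
    (SAM) or a convolutional block attention module (CBAM) extended with
    stochastic pooling. Includes a seeded synthetic-BCG generator with
    controllable rhythm regularity, the full preprocessing chain (Butterworth
    bandpass, envelope-based artifact masking, min-max normalisation, J-peak
    detection, paired 24-s/1-s segmentation), subject-disjoint evaluation
    protocols, and confusion-matrix metric arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
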