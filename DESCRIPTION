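Package: mfaren
Title: Gait Phase Recognition from Surface EMG via Multi-Scale Fuzzy
    Approximate Root Mean Entropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for recognizing gait phases (double support, single
    support, second double support, swing) from multichannel surface
    electromyography. Implements the MFAREn nonlinear feature: fuzzy
    approximate entropy with Gaussian membership, extended over multiple
    embedding scales, aggregated with a divergence-weighted average and
    fused with the window RMS; an attention convolutional network with a
    parallel LSTM branch (EMACNN) for 4-phase classification; Butterworth
    band-pass and mains-notch preprocessing with hip-angle/plantar-pressure
    phase labeling and sliding-window segmentation; a seeded synthetic
    gait-sEMG generator covering five locomotion modes; and evaluation
    utilities (confusion matrices, macro metrics, stratified k-fold,
    ablation harness).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    pracma,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
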