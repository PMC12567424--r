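Package: ecgfmha
Title: Feature-Shuffle Multi-Head Attention Autoencoder for ECG Denoising
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Removal of electrode-motion artifacts from single-lead ECG
    segments with a feature-shuffle multi-head attention autoencoder
    (FMHA-AE). Provides the network with its compiled forward/backward
    passes and Adam training loop, pure-R reference implementations of
    every block (residual convolutions, 1-D feature shuffle/unshuffle,
    multi-head self-, channel- and cross-attention), the data-preparation
    protocol (segmentation, DC removal, normalization, SNR-controlled
    noise mixing, train/test splitting, a minimal WFDB reader), synthetic
    ECG and artifact generators, SNR-improvement/PRD/RMSE evaluation
    metrics, and classical FIR/IIR/wavelet baseline denoisers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
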