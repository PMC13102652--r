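Package: mcfanet
Title: Multi-Class Fusion Attention Networks for Motor Imagery EEG Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decodes multi-class motor imagery from multi-channel EEG by
    combining filter-bank one-vs-rest common spatial pattern (CSP) filtering
    with a compact convolutional network. Per-class, per-band CSP projections
    are fused along the channel axis into a virtual-channel time series that
    preserves temporal dynamics, and a depthwise-separable convolutional
    backbone with a channel-attention gate classifies the fused
    representation. Includes leakage-free stratified cross-validation,
    filter-pair grid search, FBCSP/CSP and single-filter-set ablation
    baselines, paired statistics and gradient-based virtual-channel
    importance, plus a synthetic ERD/ERS EEG generator so the full pipeline
    can be exercised without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
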