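Package: spasmgraph
Title: Cross-Modal Temporal-Spectral Graph Networks for EEG Spasm Detection
Version: 0.1.0
Authors@R:
    person("Lena", "Ostrowski", email = "lena.ostrowski@posteo.net", role = c("aut", "cre"))
Description: Tools for detecting epileptic spasm segments in multichannel scalp
    EEG with a cross-modal graph neural network. Covers the full pipeline:
    EDF input, channel selection, resampling, zero-phase bandpass filtering,
    average referencing, z-score normalization and 5-second epoching; per-epoch
    temporal graphs from sliding-window Pearson dynamic functional connectivity
    and spectral graphs from the weighted phase lag index; a network combining
    multi-scale 1-D convolutional encoding, edge-conditioned graph convolution,
    anatomical region attention pooling, bidirectional multi-head cross-modal
    attention and gated fusion; focal-loss training with patient-grouped
    cross-validation; rank-based evaluation metrics; and gradient-times-input
    explainability with region-level evidence maps and scalp topography.
    Includes a synthetic EEG generator with controlled spasm-like events so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
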