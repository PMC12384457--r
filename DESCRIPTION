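Package: gahtnet
Title: Graph-Attention Hierarchical Temporal Networks for Motor-Imagery EEG Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the GAH-TNet architecture for motor-imagery EEG
    classification: Chebyshev spectral graph convolution over the electrode
    montage with squeeze-and-excitation channel attention and an EEGNet-style
    temporal-spatial convolutional encoder (the GATE block), followed by a
    hierarchical attention-guided deep temporal encoder (residual efficient
    channel attention, locally masked and global multi-head self-attention,
    and a causal dilated temporal convolutional network; the HADTE block).
    Includes native training (Adam, early stopping) with compiled convolution
    kernels, a minimal GDF-style recording reader/writer with cue-locked
    epoching and z-score normalisation, a synthetic event-related
    desynchronisation generator so the full pipeline runs without external
    downloads, an ablation switchboard, and evaluation protocols
    (subject-dependent splits, leave-one-subject-out folds, accuracy,
    Cohen's kappa, exact Wilcoxon signed-rank tests).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
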