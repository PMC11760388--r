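Package: afcontrast
Title: Semi-Supervised Multi-Level Contrastive Learning for Atrial
    Fibrillation Detection in Single-Lead ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for learning ECG representations for atrial fibrillation
    (AF) detection from 30-second single-lead segments. Implements a
    semi-supervised pre-training scheme with three contrastive objectives
    (temporal consistency across augmented views, channel consistency across
    simultaneously recorded leads, and label consistency across samples of
    the same rhythm class) on a two-stage encoder: a residual convolutional
    feature extractor followed by a bidirectional LSTM fusion network.
    Includes domain-knowledge augmentation for ECG (diagnostic-region
    vertical flipping and non-diagnostic T-wave masking), a preprocessing
    pipeline (resampling, zero-phase band-pass filtering, segmentation,
    z-scoring, and beat signal-quality-index filtering with Pan-Tompkins
    style QRS detection), a reader for PhysioNet WFDB records and rhythm
    annotations, a synthetic dual-lead ECG generator with ground-truth R
    peaks for fully reproducible experiments, and linear-probe / full
    fine-tuning evaluation with macro-averaged metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
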