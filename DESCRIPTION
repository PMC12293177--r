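Package: emokd
Title: Cross-Modal Knowledge Distillation for EEG-to-EOG Emotion Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a multimodal knowledge-distillation framework for
    emotion decoding from physiological signals: a multimodal EEG+EOG teacher
    network with convolutional frontends, dual-stream transformer encoders and
    gated interaction fusion; a structurally aligned EOG-only student with
    heterogeneous deep fusion; and a two-phase distillation procedure in which
    a dynamic feedback step adapts the teacher to the student through a bilevel
    gradient. Includes a trial-structured synthetic EEG+EOG cohort generator
    with controllable cross-modal shared information, leakage-safe trial-wise
    splitting, the trial-wise evaluation protocol (accuracy, F1, paired
    t-tests), ablation and train/test-leakage experiment drivers, and a YAML
    configured pipeline runner. All networks run on a small built-in
    reverse-mode automatic differentiation engine.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    signal,
    yaml,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
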