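Package: doafuse
Title: Depth-of-Anesthesia Index Fusion from Frontal EEG Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates depth of anesthesia (DoA) on a 0-100 scale from
    single-channel frontal EEG. Implements a five-step artifact-removal and
    epoching chain (outlier interpolation, band-pass FIR filtering, stationary
    wavelet EOG suppression, inverse-filter EMG rejection, resampling to
    100 Hz); extracts four per-minute features (permutation entropy,
    BetaRatio, 95% spectral edge frequency, and the bispectral SynchFastSlow
    ratio); and fuses them into a DoA index with a small feedforward neural
    network trained by backpropagation, with a linear epsilon-SVR baseline.
    Includes state classification against the standard 0-100 index bands,
    per-state sensitivity and accuracy, Pearson correlation, Bland-Altman
    agreement, leave-one-subject-out cross-validation, feature-ablation
    studies, and a seeded synthetic anesthesia-EEG generator (state-dependent
    spectra, quadratic phase coupling, burst suppression, EOG/EMG artifacts)
    so every stage is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
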