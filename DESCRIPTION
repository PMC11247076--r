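Package: arousalNet
Title: Automatic Detection of Cortical Arousals in Polysomnography with a
    1D U-Net
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end detection of cortical arousals in overnight
    polysomnography (PSG). Implements the full pipeline: EDF signal input,
    antialiased downsampling of EEG/EOG/chin-EMG channels to 50 Hz with
    18-minute moving mean/RMS normalization, a fully convolutional 1D U-net
    that maps the three-channel input to a 50 Hz arousal-probability track,
    training with binary cross-entropy, Adam, a cyclical learning rate and
    early stopping on sample AUPRC, conversion of probabilities to discrete
    events by thresholding, patience merging and minimum-length filtering,
    event-level evaluation (overlap matching, micro F1, arousal-index error,
    Pearson correlation), and a clinically oriented bias analysis of the
    arousal-index error across diagnosis, age and sex groups (Shapiro-Wilk,
    Kruskal-Wallis, Dunn post-hoc with Bonferroni correction, Cohen's d
    effect sizes). A synthetic polysomnogram generator with ground-truth
    arousals, hypnograms and metadata makes every stage testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
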