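Package: mltlsmote
Title: Hybrid SMOTE/Tomek-Link Resampling for Imbalanced Multi-Label Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and correcting label imbalance in
    multi-label datasets. Implements per-label imbalance ratios (IRLbl,
    MeanIR, MaxIR, CVIR), a hybrid resampler that oversamples minority
    labels by SMOTE interpolation and then cleans majority labels with
    Tomek links (ML-TLSMOTE), the standard multi-label evaluation metrics
    (Hamming loss, ranking loss, average precision, micro F1, macro AUROC),
    six multi-label classification strategies (binary relevance, classifier
    chains, label powerset, RAkEL, calibrated label ranking, MLkNN) over
    pluggable base learners, a synthetic generator with controllable
    imbalance structure, readers and writers for MEKA-style multi-label
    ARFF and CSV, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    foreign,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
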