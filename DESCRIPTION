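Package: p300balance
Title: Data Balancing Techniques for P300-Based Brain-Computer Interfaces
Version: 1.0.0
Author: Package Author
Maintainer: Package Author <author@example.com>
Description: Simulation and analysis pipeline for studying class-imbalance
    correction in P300 oddball brain-computer interfaces. Generates synthetic
    multichannel EEG sessions with a controllable P300 evoked response,
    preprocesses them into standardized event-related-potential feature
    matrices, implements five oversamplers (random oversampling, SMOTE,
    borderline-SMOTE, SVM-SMOTE, ADASYN) and three undersamplers (random
    undersampling, neighborhood cleaning rule, Tomek links) from scratch,
    trains soft-margin SVM target classifiers including a weighted
    undersampling bagging ensemble and a class-weighted regularization
    variant, and evaluates block-level selection accuracy, recall, precision,
    F1, information transfer rate, and support-vector geometry.
License: MIT
Encoding: UTF-8
Imports:
    e1071,
    signal,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
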