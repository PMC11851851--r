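Package: painsense
Title: EEG-Based Objective Pain Assessment Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for objective pain assessment from
    multichannel EEG with per-trial pain-rating event markers. Reads
    BrainVision-style recordings, decodes 1-10 pain ratings from event ids,
    cuts variable-length epochs, and cleans signals (1 Hz high-pass, 50 Hz
    notch, downsampling to 500 Hz, extended-Infomax independent component
    analysis with artifact rejection). Features are per-channel Daubechies-4
    discrete wavelet decompositions (level 5) summarised by per-band
    statistics. Training data can be expanded by multiplicative scaling,
    bounded uniform noise injection and Hilbert-transform frequency shifting,
    and balanced by SMOTE. Binary (pain/no-pain) and ternary (low/moderate/
    high) classifiers - SVM, k-NN, random forest, a 1-D convolutional network
    and a stacked LSTM - are evaluated under stratified 80:20 holdout and
    10-fold cross-validation with accuracy, precision, recall, F1 and RMSE,
    with leakage guards keeping augmentation and standardisation inside
    training folds. A seeded synthetic-EEG generator makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    ranger,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
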