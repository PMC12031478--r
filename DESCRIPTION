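Package: silentspeech
Title: Silent-Speech Letter Classification from Chin EMG and Piezoelectric Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classification pipeline for silent text input from a two-sensor
    chin wearable combining surface electromyography (EMG) and a piezoelectric
    (PZT) vibration transducer. Implements time- and frequency-domain feature
    extraction for biosignals, recursive feature elimination, SMOTE
    feature-space oversampling, randomized raw-signal augmentation operators,
    grid-searched feature-based classifiers (SVM, decision tree, random
    forest), a 1D-convolutional feature-extraction network with adaptive
    pooling, a Siamese few-shot classifier trained with a cosine-similarity
    loss against per-class reference feature vectors, and a Parallel
    Multi-Layer Data Fusion (PMLDF) architecture that fuses the two sensor
    streams layer by layer. A seeded synthetic two-channel trial generator
    with controllable class separability makes every stage testable without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    rpart,
    ranger,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
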