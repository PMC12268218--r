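Package: emoseq
Title: Facial Emotion Recognition from Action-Unit Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for recognising discrete emotions from per-frame facial
    action unit (FAU) time series extracted from selfie-style smartphone
    videos. Provides OpenFace-dialect feature readers with face-gap filling,
    energy-based detection of the emotional phase of a recording, difficulty
    homogenised subject-level data partitioning via leave-one-subject-out SVM
    scoring, a support vector machine baseline, gated recurrent unit (GRU)
    sequence classifiers with average, attention and depthwise-convolution
    pooling heads for binary (valence) and 16-class emotion recognition, and a
    complete evaluation suite (unweighted average recall, balanced accuracy,
    Cohen and Fleiss kappa, bootstrap confidence intervals, binomial tests)
    for comparing classifiers with human observers. A seeded synthetic corpus
    generator emulating the structure of a Wizard-of-Oz smartphone video study
    makes every stage testable without access to private video data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    caret,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
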