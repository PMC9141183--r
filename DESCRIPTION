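Package: eegfusion
Title: Cross-Subject EEG Emotion Recognition via Feature Selection and
    Multi-Classifier Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A pipeline for subject-independent recognition of emotional
    valence from multi-channel EEG. Recordings are trimmed, cut into 10-second
    windows and reduced to a 15-electrode montage; each window is summarised by
    a 249-dimension battery of time-domain, band-power and nonlinear-dynamics
    features (sample, approximate, differential and wavelet entropy, largest
    Lyapunov exponent, Higuchi fractal dimension, rescaled-range Hurst exponent
    and Hjorth parameters). Features are filtered by mutual information,
    refined by sequential forward floating selection, and classified by a
    multi-classifier fusion scheme that feeds cross-fitted class probabilities
    of KNN, SVM and random-forest bases back into a final classifier.
    Evaluation supports hold-out and leave-one-subject-out protocols, and a
    synthetic generator produces DEAP-shaped recordings with controllable
    class-conditional band-power structure so the whole pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    randomForest,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
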