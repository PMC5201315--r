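Package: drivefatigue
Title: Driver Fatigue Analysis from Physiological Signals and Reaction Time
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse driver mental state from simulator-driving
    sessions: synthetic generation of EEG, RR-interval and choice
    reaction-time records with a three-level fatigue trajectory; spectral
    feature extraction (Welch band power, alpha/beta ratio indices, heart
    rate, RR-interval standard deviation, Haar wavelet denoising); grey
    relational analysis ranking physiological factors against reaction
    time; a hierarchical two-stage soft-margin RBF support vector machine
    classifier whose penalty and kernel width are tuned by a real-coded
    genetic algorithm with K-fold cross-validation fitness; and
    confusion-matrix evaluation with stage-wise sensitivity, specificity,
    precision and reaction-time growth-rate reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
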