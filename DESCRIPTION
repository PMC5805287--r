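Package: ewnne
Title: Evolutionary Wavelet Neural Network Ensembles for Binary
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Trains wavelet neural networks for binary biomedical
    classification with a (mu+lambda) evolution strategy that optimises
    every network parameter concurrently (input selection switches, input
    weights, wavelet dilation, translation and rotation, activation
    identity, hidden-unit activity, shortcut weights and bias), then
    prunes a pool of evolved networks into a compact majority-voting
    ensemble with a genetic algorithm whose fitness combines the
    individual accuracies of the selected classifiers with their joint
    voting accuracy.  Includes the two-spiral benchmark generator, a
    synthetic patient-structured clinical data generator,
    patient-grouped stratified cross-validation, and confusion-matrix
    statistics (accuracy, sensitivity, specificity, Matthews correlation
    coefficient) with per-patient aggregation of record-level
    predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
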