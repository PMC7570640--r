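Package: tbiEEG
Title: LSTM ECOC-SVM Classification of Non-Severe Traumatic Brain Injury from Resting-State EEG
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Three-class classification of resting-state EEG recordings
    (healthy, mild traumatic brain injury, moderate traumatic brain injury)
    with a single-cell long short-term memory (LSTM) network whose final
    hidden-state activations feed a one-vs-one error-correcting output code
    support vector machine decoded by Hamming distance. Implements the fixed
    preprocessing chain (50 Hz notch, 0.1-100 Hz bandpass, decimation to
    100 Hz, artifact excision, 60 s window reshaped to 60 steps x 63
    channels x 100 samples), backpropagation-through-time training with
    ADAM or SGD-with-momentum, a bootstrap plus stratified 3-fold
    cross-validation evaluation protocol with percentile confidence
    intervals, a hill-climbing hyperparameter sweep, and a seeded synthetic
    resting-state EEG generator with class-dependent alpha/theta spectral
    structure so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'montage.R'
    'simulate.R'
    'welch.R'
    'preprocess.R'
    'lstm.R'
    'ecoc.R'
    'evaluate.R'
    'sweep.R'
    'edf.R'
    'io.R'
    'pipeline.R'
    'zzz.R'
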