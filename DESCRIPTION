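Package: graspADL
Title: Grasp-Dynamics Feature Extraction and Classification for Hand-Tracking
    Data
Version: 0.1.0
Authors@R:
    person("Grasp", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing skeletal hand-tracking recordings of
    activities-of-daily-living (ADL) grasps. Converts per-frame joint
    coordinates from a global coordinate system into a palm-anchored hand
    coordinate system (removing gross arm motion), median-filters the
    channels, computes geometric, windowed time-domain and frequency-domain
    grasp features normalised by a per-subject hand length, and evaluates
    radial-basis-function support vector machine and convolutional neural
    network classifiers under k-fold cross-validation. Includes a
    forward-kinematic synthetic grasp generator so the full pipeline is
    testable without access to motion-capture hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Collate:
    'hand-model.R'
    'trial-io.R'
    'preprocess.R'
    'features-geometric.R'
    'features-windowed.R'
    'feature-matrix.R'
    'svm.R'
    'cnn.R'
    'classify-eval.R'
    'synthetic.R'
    'RcppExports.R'
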