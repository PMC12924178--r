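Package: bdtmodel
Title: Beam Delivery Time Modelling for Pulse-Scanned Proton Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and machine-learning analysis of beam delivery time
    (BDT) for pulse-scanned proton therapy systems of the Mevion S250i
    Hyperscan type. Provides a synthetic machine-log simulator encoding the
    delivery physics (range-modulator energy levels, adaptive-aperture leaf
    motion, spot-to-pulse splitting, three-regime inter-pulse timing with
    heteroscedastic inter-fraction noise), feature engineering from pulse-level
    logs, random-forest regression of inter-pulse times with cross-validated
    randomized hyperparameter search, interval-stratified error metrics,
    Shapley-value explainability (exact coalition enumeration and a fast
    interventional tree algorithm) with physically-motivated feature groups,
    and downstream applications: cumulative delivery-time reconstruction for
    volumetric repainting and breathing-phase interplay mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ranger,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
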