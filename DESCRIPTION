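Package: satlba
Title: Neurally Constrained Linear Ballistic Accumulator Analysis of
    Speed-Accuracy Tradeoff
Version: 0.1.0
Authors@R:
    person("satlba", "developers", email = "satlba@example.org",
           role = c("aut", "cre"))
Description: Fits a linear ballistic accumulator (LBA) model of two-choice
    decisions under speed, neutral and accuracy emphasis, with threshold and
    drift-rate constraints derived from frontal-eye-field recordings: the
    speed-setting threshold is fixed at 1.2 times the accuracy-setting
    threshold, the speed-setting drift-rate standard deviation is fixed at 1
    to satisfy the model's scaling property, and accuracy-emphasis trials are
    modelled as a mixture of accuracy-setting and speed-setting (cue-neglect)
    decisions. Provides closed-form defective first-passage densities,
    trial and trajectory simulation, a differential-evolution MCMC sampler
    with convergence diagnostics, synthetic-data generation, posterior
    predictive checks, and command-line entry points for an end-to-end
    parameter-recovery pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    graphics,
    grDevices,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
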