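Package: cointransfer
Title: Transfer Scores for Bayesian Cue Combination in the Coin Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for sensorimotor estimation
    experiments in which observers combine a learned Gaussian location prior
    with noisy dot-cloud likelihood information ("coin task"). Simulates
    cohorts of observers following Bayesian and non-Bayesian strategies,
    recovers per-participant sensory-weighting slopes and subject-specific
    variance proxies, quantifies generalization to novel prior/likelihood
    pairings with a transfer score, computes a per-trial optimality index,
    and compares candidate strategy models by BIC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
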