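Package: forceshare
Title: Optimal Control and Bayesian Inference of Bimanual Force Sharing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models how two fingers, one per hand, share a static isometric
    force target under signal-dependent motor noise. Implements a quadratic
    cost trading off expected squared target error, absolute effort and
    strength-normalized effort, with its closed-form optimal force commands
    and optimal force share; calibration of each finger's coefficient of
    variation (robust regression of force SD on mean) and maximum voluntary
    contraction from unimanual recordings; an adaptive Metropolis-within-Gibbs
    sampler for the simplex-constrained cost weights and per-participant
    observation variances; model comparison across all weight subsets by
    posterior-averaged log-likelihood, Bayes factors and AIC; and a seeded
    synthetic-data generator so the complete pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: MASS, stats, utils, graphics, grDevices, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
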