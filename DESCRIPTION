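Package: metacontrolr
Title: Dual-Systems Reinforcement Learning and Metacontrol in a Two-Step
    Stakes Task
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation, model fitting and statistical inference for a
    child-friendly two-step sequential decision task with deterministic
    transitions, drifting treasure rewards and a 1x/5x stake manipulation.
    Implements a hybrid model-based/model-free reinforcement-learning agent
    with stake-conditioned weighting parameters, per-subject maximum
    likelihood estimation of those parameters (the difference of the two
    weights is the metacontrol score), model-agnostic behavioural metrics,
    a synthetic cohort generator with a Gaussian-copula individual
    difference structure, and the inferential toolkit used on such cohorts:
    Pearson correlations with Fisher-z intervals, Welch t tests, Bonferroni
    family-wise control, percentile-bootstrap mediation and exact power
    analysis for correlations.
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
RoxygenNote: 7.3.3
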