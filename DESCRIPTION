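Package: beadsampling
Title: Two-Stage Decision Models for Costly Information Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing sequential information sampling in the
    bead-sampling (jar inference) task, where observers draw costly samples
    before judging which of two urns they came from. Provides ideal-observer
    calculations (expected accuracy, expected gain, optimal sample size) and
    behavioral optimality measures; a sixteen-model family of one- and
    two-stage logistic stopping models with coupled lognormal decision-time
    mixtures and joint choice/decision-time likelihoods; per-participant
    two-step maximum-likelihood fitting; fixed-effects (AICc/BIC) and
    random-effects (protected exceedance probability) model comparison with a
    cost-evidence strategy index; bespoke behavioral statistics including
    Hartigan's dip test, log decision-time Gaussian mixtures, and
    cluster-based permutation tests on running correlation curves; and a
    synthetic-agent simulator that emulates the full task design for
    parameter- and model-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    mclust,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    jsonlite,
    optparse
Config/testthat/edition: 3
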