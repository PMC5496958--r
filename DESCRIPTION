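Package: moralchoice
Title: Value-of-Life Models for Forced-Choice Moral Decisions in Road Traffic
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of two-alternative forced-choice
    road-traffic dilemmas in which a driver must choose which of two
    obstacles to hit. Provides balanced experiment schedules built from a
    round-robin 1-factorization of the complete pairing graph, choice
    simulation from a latent value-of-life scale with condition-specific
    lapse rates, penalized logistic paired-comparison models (per-pairing,
    per-obstacle, and per-cluster predictor families with starting-lane and
    lane-bias terms), BIC and cross-validated model comparison, bottom-up
    clustering of sparing frequencies with BIC-based cluster-count
    selection, empty-lane error-rate estimation, nested likelihood-ratio
    condition contrasts, and outlier-subject exclusion.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
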