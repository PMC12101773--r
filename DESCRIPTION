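Package: goalmomentum
Title: Momentum-Based Valuation Models of Extended Goal Pursuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a multi-goal token-collection ("suits") task and fits a
    family of goal-valuation agents to round-by-round choice data: a TD-momentum
    model in which accrued fractional progress and a learned speed of progress
    jointly build goal value, alongside prospective (discounted belief rollout),
    retrospective, hybrid, TD-persistence and Rescorla-Wagner + choice-kernel
    competitors. Provides a hierarchical goal-then-action stay/switch policy,
    latent-goal likelihoods over interleaved card choices and periodic goal
    probes, maximum-likelihood fitting with AIC/BIC and block-wise
    cross-validation, synthetic-participant cohort generation, behavioral
    signature analyses, parameter/model recovery studies, and normative
    simulations in drifting and reversing environments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
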