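Package: twostepEEG
Title: Hybrid Reinforcement Learning and Single-Trial EEG Regression for
    the Two-Step Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates the two-step sequential decision task, fits the
    hybrid model-free/model-based SARSA(lambda) reinforcement-learning
    model family by maximum likelihood with BIC model selection, extracts
    trial-wise signed reward prediction errors, and relates them to
    feedback-locked EEG: per-subject single-trial robust (Huber) regression
    over channel-by-time maps with FDR-corrected group statistics,
    FRN/P3 component-window summaries, and second-level robust regression
    of the RPE modulation onto trait impulsivity, compulsivity and
    model-basedness (w). Includes a synthetic cohort generator with
    planted, trait-linked ERP modulation for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lme4,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
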