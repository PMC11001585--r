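Package: ruleswitch
Title: Simulation and Analysis of Rule-Switch Learning, Dopamine Prediction
    Errors and Fiber Photometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying cue-action-outcome learning under changing
    task rules. Provides a generative model of an auditory two-alternative
    rule-switch task (deterministic and probabilistic variants), temporal-
    difference reinforcement-learning agents (on-policy SARSA, off-policy
    Q-learning, and a state-value learner) whose TD errors model striatal
    dopamine reward prediction errors, behavioral summary statistics
    (accuracy, response bias, learning rate, performance staging, session
    truncation, stay/switch splits), a session-based logistic-regression
    model of trial-by-trial choice with cross-validated model comparison,
    and a fiber-photometry processing chain (smoothing, per-trial dF/F,
    robust z-scoring, prominence-based peak extraction in region-specific
    epoch windows). Synthetic-data generators with known ground truth
    exercise every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
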