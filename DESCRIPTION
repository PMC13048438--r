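Package: consensusarena
Title: Best-of-N Collective Decisions from Movement-Based Opinions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of embodied best-of-n consensus
    experiments in which groups of avatars must converge on the largest of
    four circular sites in an open arena. Provides a kinematic agent-based
    simulator with noisy size perception, social copying and a logistic
    switch hazard; extraction of movement-based opinion time series from
    trajectories; social-disagreement (DeltaSocial) and spatial metrics
    (center-of-mass distance, approach speed); per-second switch-event
    construction for hazard analysis; trial outcome scoring with
    success-probability summaries; and a mixed-effects inference layer
    (logistic and linear mixed models, Type II Wald chi-square tests,
    estimated marginal means with false-discovery-rate adjusted pairwise
    contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    lme4,
    car,
    emmeans,
    sandwich,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
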