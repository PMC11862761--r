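Package: vesselgame
Title: Headless Blood-Vessel Cutting Game for Field-of-View Experiments
Version: 0.1.0
Authors@R: person("Vessel Game", "Developers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A scriptable, deterministic re-implementation of a blood-vessel
    cutting serious game used to quantify the effect of a restricted circular
    field of view on visual-search task performance. Provides procedural
    generation of low-contrast vessel scenes, a headless event-driven game
    engine with cut detection and attempt/timer bookkeeping, a transparent
    lognormal simulator of participant cohorts, and the statistical pipeline
    (t-based confidence intervals, Welch two-sample tests, Cohen's d, percent
    increases, and noncentral-t sample-size planning) used to analyse trial
    logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
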