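Package: matg
Title: Simulation, Cognitive Modeling and Fitting for the Multi-Arm Trust Game
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the multi-arm trust game (MATG), an iterated trust
    game in which a sender splits a per-round endowment among several
    receivers that are only intermittently available to interact, receive a
    multiplied amount, and return a share. Provides the exact game mechanics
    with scripted confederate receiver policies, an instance-based-learning
    cognitive agent with activation-weighted blending, trust and trust-invest
    accumulators with a state-dependent reward scheme, procedural utility
    learning over allocation-adjustment rules, lesioned model variants, grid
    search fitting by correlation and root-mean-squared deviation, yoked
    inference of latent trust accumulators from behavioral logs, and a
    synthetic cohort generator emulating the empirical allocation dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
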