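Package: volatilearn
Title: Valenced Reinforcement Learning Under Volatility with Pupillometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying adaptive learning in a three-block win/loss
    volatility task: schedule generation and validation, Rescorla-Wagner
    agents with valence- and block-specific learning rates, MAP and MCMC
    model fitting with integrated-BIC model comparison, parameter-recovery
    and posterior-predictive harnesses, switch/stay and learning-rate
    adjustment statistics (mixed ANOVA with Greenhouse-Geisser correction,
    Welch and one-sample t-tests, Fisher r-to-z comparison of
    correlations), a pupillometry pipeline (blink interpolation, epoching,
    condition subtraction series, cluster-based permutation tests), and a
    synthetic-cohort generator emulating three participant groups so that
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    car,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
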