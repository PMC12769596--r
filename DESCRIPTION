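Package: mbfd
Title: Design and Analysis of Individually Randomized Multiple Baseline
    Factorial Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and analysing individually randomized
    multiple baseline factorial designs (MBFDs), in which every participant
    starts under standard of care, transitions at a staggered, randomized
    time into one of two interventions, and then receives their sequential
    combination. Provides design construction and validation, balanced
    randomization, simulation of continuous longitudinal outcomes from a
    random-intercept model, estimation by restricted maximum likelihood
    linear mixed models with Satterthwaite degrees of freedom and by
    generalized estimating equations with exchangeable working correlation
    (robust and Mancl-DeRouen bias-corrected variances), and a Monte Carlo
    engine for bias, type I error and power under user-defined scenario
    grids.
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
    lme4,
    lmerTest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
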