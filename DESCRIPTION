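Package: opioidblockr
Title: Central Opioid Receptor Blockade Modeling and Experiment Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models central mu-, delta-, and kappa-opioid receptor blockade
    after intravenous naloxone and oral naltrexone from published positron
    emission data. Fits the constrained log-logistic (Hill slope 1)
    dose-blockade model by non-linear least squares, recovers first-order
    absorption and elimination kinetics of the central blockade (including
    the Lambert W inversion of the one-compartment peak-time identity),
    simulates blockade-time profiles for bolus and infusion regimens by
    closed-form superposition, scales the mu-opioid ED50 to the delta and
    kappa receptors by relative affinity, and plans experiments: duration
    of full (>90%) blockade, minimum assessment delay, washout intervals,
    minimum doses, and drug-cost estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
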