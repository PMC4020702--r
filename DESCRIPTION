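Package: jointharvest
Title: Joint Known-Fate and Brownie Tag-Recovery Estimation of Harvest
    and Survival Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood estimation of harvest and annual survival
    rates for hunted wildlife populations by jointly modelling three data
    streams: Kaplan-Meier staggered-entry known-fate records from
    radio-marked animals (monthly tagging-to-harvest survival), dead
    recoveries of reward-tagged animals in a Brownie tag-recovery model,
    and binomial harvest counts of transmitter-fitted animals. The joint
    likelihood separates tagging-to-harvest survival from the harvest rate,
    removing the negative bias that pre-season mortality induces in the
    standard Brownie estimator. Includes flexible factor-structured model
    specifications with AICc comparison and Akaike weights, a test for a
    transmitter effect on harvest probability, delta-method standard errors
    for cumulative survival, and a Monte Carlo engine for studying estimator
    bias, CV, and CV(RMSE) across transmitter and tag allocation designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
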