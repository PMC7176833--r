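Package: pericost
Title: Societal Cost-of-Illness Modelling for Perinatal Depression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for estimating the societal economic burden
    of maternal depression over pregnancy and the first year postpartum.
    Generates seeded synthetic perinatal cohorts with interview waves,
    depression-status dynamics, overdispersed service utilisation and
    attrition; computes provider unit costs by gross costing with a
    patient-day-equivalent hospital split; values household care-seeking
    costs (opportunity cost of the mother's time, travel, user fees) and
    catastrophic expenditure shares; constructs socioeconomic outcomes
    (regression-imputed income, per-capita income, a multiple correspondence
    analysis wealth index); and runs a four-state perinatal Markov cohort
    model with gamma-distribution probabilistic sensitivity analysis,
    reporting mean costs with 90 percent uncertainty intervals by
    depression status.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
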