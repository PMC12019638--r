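Package: depcare
Title: Markov and Macrosimulation Projection of Depressive Symptoms and
    Social Care Costs Under Housing Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Couples a multi-state Markov cohort model of depressive-symptom
    progression in an ageing population with a cell-based macrosimulation of
    unpaid and formal home-care demand and costs. Transition probabilities
    come from lagged multinomial logistic regressions of depression severity
    on housing quality and socio-demographics; care utilisation and weekly
    hours come from cross-sectional multinomial and linear models. Housing
    intervention scenarios cap the number of housing problems, and
    sensitivity machinery covers accelerated/delayed progression,
    intervention-effectiveness scaling, replacement versus opportunity
    costing of unpaid care, and Monte Carlo credible intervals. A seeded
    synthetic panel generator emulates the longitudinal survey structure the
    models expect, so the whole pipeline runs without restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    nnet,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
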