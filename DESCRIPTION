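Package: dmscreen
Title: Cost-Effectiveness Modelling of Population-Based Type 2 Diabetes Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Markov cohort state-transition model of type 2 diabetes
    progression (nephropathy, neuropathy, retinopathy, coronary heart
    disease and stroke tracks) coupled to a one-time population screening
    front-end, for lifetime cost-effectiveness analysis of national
    diabetes screening programs. Provides validated parameter bundles
    (annual transition probabilities, screening test characteristics,
    complication costs, utility weights, discounting), a synthetic cohort
    generator emulating a national adult population aged 40 and over
    (age/sex structure, Gompertz life tables, risk-factor and undiagnosed
    diabetes prevalence surfaces, incidence estimation from prevalence via
    a discrete illness-death model), an expected-value cohort engine with
    an individual-level Monte Carlo cross-check, discounted cost and QALY
    accrual with ICER computation and purchasing-power-parity currency
    conversion, and a one-way sensitivity and scenario analysis engine
    with tornado-style output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
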