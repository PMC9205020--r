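Package: metalage
Title: Urinary Metal Mixtures, Biological Aging, and Osteoarthritis Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying urinary metal mixtures and
    osteoarthritis risk with biological aging as a mediator. Provides
    limit-of-detection handling and creatinine correction for urinary
    biomarkers, Klemera-Doubal biological age estimation, the phenotypic
    age closed form, survey-weighted single-metal logistic and linear
    regression with trend tests and false-discovery-rate correction,
    weighted quantile sum (WQS) regression for mixtures, and parallel and
    serial causal mediation via quasi-Bayesian Monte Carlo simulation.
    Includes a synthetic cohort generator with a configurable
    metal-to-aging-to-outcome structure so every stage is testable
    without external survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    sandwich,
    foreign,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
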