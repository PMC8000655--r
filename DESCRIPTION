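Package: screenCEA
Title: Markov Cohort Cost-Effectiveness Analysis of Breast-Cancer Screening Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic comparison of digital breast tomosynthesis (DBT)
    and abbreviated breast MRI (AB-MRI) for two-yearly screening of women at
    intermediate risk of breast cancer due to dense breast tissue. Implements a
    per-round screening decision tree, a Markov cohort state-transition model
    over a 30-year horizon with discounted cost and QALY accrual, incremental
    cost-effectiveness ratios and dominance classification, examination-price
    threshold solving, one-way deterministic sensitivity analysis (tornado),
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves, and an individual-level microsimulation used as a brute-force
    cross-validation oracle for the cohort engine.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
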