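Package: hearcua
Title: Cost-Utility and Budget-Impact Modelling of Hearing-Aid Provision
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for cost-utility evaluation of hearing-aid
    provision in older adults: EQ-5D-5L health-state scoring against a
    pluggable value-set tariff, WHO better-ear severity grading, a 3-year
    decision-tree comparison of no-aid vs unilateral vs bilateral fitting,
    a 15-year three-state (mild/moderate/severe) cohort Markov model with
    annual cycles, discounting and periodic device replacement, incremental
    cost-effectiveness arithmetic (ICER, dominance, net monetary benefit,
    willingness-to-pay classification), and a national budget-impact
    calculator in crore INR. Ships a synthetic-cohort generator that
    reproduces the arm-by-severity structure of a 2023 survey of 636
    hearing-impaired older adults so the full pipeline is testable without
    microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
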