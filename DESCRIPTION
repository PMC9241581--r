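Package: egfrcea
Title: Cost-Effectiveness Modelling of First-Line Treatments for EGFR-Mutated NSCLC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markov cohort modelling toolkit for cost-effectiveness analysis of
    first-line treatments for advanced EGFR-mutated non-small cell lung cancer.
    Implements Weibull survival extrapolation with hazard-ratio adjustment,
    parametric survival fitting with AIC/BIC model selection, a weekly-cycle
    three-state (progression-free / progressed / dead) cohort simulation with
    discounted cost and QALY accrual, cost-effectiveness frontier construction
    with strict and extended dominance, one-way deterministic sensitivity
    analysis, scenario analyses, and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves. Ships transcribed UK and China
    parameter fixtures and synthetic-data generators for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
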