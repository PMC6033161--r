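Package: quitroi
Title: Markov Cohort Return-on-Investment Modelling for Smoking Cessation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state (current smoker, former smoker, dead) annual-cycle
    Markov cohort model for forecasting lifetime healthcare costs, life-years
    and quality-adjusted life-years (QALYs) of smokers who quit versus those
    who continue smoking. Country inputs (life tables, smoking and disease
    prevalence, relative risks, disease costs, utilities, smoker counts) are
    read from delimited text files; smoking-status-specific mortality and
    disease prevalence are derived by population-attributable decomposition.
    Packages of cessation interventions are compared via incremental
    cost-effectiveness ratios, net monetary benefit, benefit-cost ratios and
    deaths averted, with parameter uncertainty propagated by Monte Carlo
    probabilistic sensitivity analysis and summarised as cost-effectiveness
    acceptability curves. Includes a synthetic country-dataset generator and
    an England per-smoker worked example for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
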