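Package: statinbenefit
Title: Risk-Based Versus Individualized-Benefit Statin Eligibility Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing statin-eligibility strategies in primary
    prevention of cardiovascular disease: conventional absolute 10-year-risk
    thresholds versus individualized-benefit thresholds based on the predicted
    individual absolute risk reduction (iARR) from LDL-C lowering. Includes a
    synthetic survey-weighted cohort generator, a pluggable sex-specific
    Cox-type 10-year risk engine with recalibration, the benefit chain
    (LDL-C reduction, relative risk, iARR, iNNT), calibration of benefit
    thresholds to match events prevented, survey-weighted population
    projections with bootstrap confidence intervals, and concordance
    reporting between strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
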