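Package: bpascreen
Title: Validation of an Emergency-Department Diabetes-Screening Alert
    Algorithm
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to validate a rule-based best-practice-advisory (BPA)
    that flags emergency-department patients eligible for HbA1c diabetes
    screening. Provides a synthetic electronic-health-record cohort
    generator with controlled discordance between the structured record
    and the full chart, the screening rule engine, a chart-review
    reference standard, stratified verification sampling with
    Horvitz-Thompson weights, and diagnostic-accuracy statistics:
    sensitivity, specificity, predictive values, likelihood ratios with
    delta-method intervals, prevalence-based predictive-value calculus,
    and a weighted logistic ROC/AUC with bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
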