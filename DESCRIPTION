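Package: rrrdiet
Title: Sex-Stratified Dietary Pattern Extraction by Reduced Rank Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for extracting zinc- and polyunsaturated-fatty-acid-driven
    dietary patterns from two-day 24-hour recall data by reduced rank
    regression, and for relating them to serum fatty-acid biomarkers.
    Includes an energy-intake misreporting screen built on predicted total
    energy expenditure, a variance-component shrinkage estimator of usual
    food-group intake, residual-method energy adjustment, simplified pattern
    scores with quintile assignment, trend / chi-square / partial-correlation
    tests, covariate-adjusted outcome regressions, and a synthetic cohort
    generator with planted pattern structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    foreign,
    haven,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
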