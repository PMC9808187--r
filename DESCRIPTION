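Package: eciaf
Title: Composite Anthropometric Failure Indices for Child Malnutrition Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring the overall burden of early childhood
    malnutrition from household surveys. Computes LMS-based anthropometric
    z-scores (height-for-age, weight-for-age, weight-for-height, BMI-for-age)
    with the restricted tail adjustment and biological-plausibility flagging,
    classifies children into the mutually exclusive groups of the composite
    index of anthropometric failure (CIAF) and its extension to over-nutrition
    (eCIAF), estimates design-weighted prevalences with Taylor-linearized
    confidence intervals under two-stage stratified cluster designs, compares
    failure configurations between surveys by two-group configural frequency
    analysis, profiles full z-score distributions over a quantile grid with
    cluster-bootstrap bands, and simulates two-stage cluster surveys with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    quantreg,
    optparse
Config/testthat/edition: 3
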