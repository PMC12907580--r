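Package: heattol
Title: Heat Tolerance Test Metrics, Classification and Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for the standardized 120-minute treadmill heat
    tolerance test (HTT). Computes thermoregulatory and cardiovascular metrics
    from rectal temperature and heart rate time series (areas under the curve
    above physiological thresholds, rate of rise, thermal-circulatory ratio,
    plateau statistics), body-size, sweat and partitional-calorimetry
    quantities, applies the published battery of heat-intolerance
    classification criteria, and summarises cohorts with contingency-table
    statistics (Yates-corrected chi-square, Fisher exact tests) and Hedges' g
    effect sizes. Includes a seeded synthetic cohort generator calibrated to
    published sex- and acclimation-specific group statistics so the full
    pipeline can be exercised without access to raw participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    yaml,
    withr
Config/testthat/edition: 3
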