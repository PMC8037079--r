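Package: gertality
Title: GERtality Score Development and Evaluation for Geriatric Trauma Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for developing and evaluating additive in-hospital
    mortality risk scores for geriatric trauma patients. Implements the
    GERtality score (one point each for age >= 80 years, maximum AIS >= 4,
    packed red-blood-cell transfusion before ICU admission, ASA physical
    status >= 3, and GCS <= 13), the Geriatric Trauma Outcome Score (GTOS),
    and the Injury Severity Score (ISS); the score-development workflow of
    dichotomizing registry variables, screening them by mortality-based
    cut-off search and univariable or multivariable odds ratios, and
    assembling the selected criteria into a score; ROC/AUC comparison of
    competing scores with DeLong or bootstrap confidence intervals; and a
    reproducible synthetic trauma-registry generator with a known logistic
    mortality model so the whole pipeline can be exercised without access
    to restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
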