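Package: qrlnorm
Title: Quantile Regression Normative Limits and Color-Flagging for
    Clinical Reference Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds age-conditional normative limits for clinical
    thickness metrics (OCT circumpapillary RNFL and ganglion cell layer
    metrics) from reference databases of healthy eyes.  Fits 50th, 5th
    and 1st percentile quantile regression lines with age and disc-area
    covariates via an exact interior-point linear-programming solver,
    compares them to a constant-variance Gaussian null model, assigns
    green/yellow/red flags to test eyes, quantifies how flagging changes
    between a small and a large reference database (transition tables,
    sensitivity/specificity/accuracy deltas, screening projections), and
    attributes the difference to sampling error by Monte Carlo
    subsampling of regression coefficients.  Includes a calibrated
    synthetic-cohort generator for reference and glaucomatous test
    populations.
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
    withr,
    quantreg
Config/testthat/edition: 3
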