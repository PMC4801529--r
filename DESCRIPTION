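Package: bitterpls
Title: Robust Partial Least Squares Calibration of Electronic-Tongue
    Bitterness Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calibrates electronic-tongue sensor arrays against human
    taste-panel bitterness scores with a robust partial least squares
    (RSIMPLS-style) regression built on minimum covariance determinant and
    robust principal component estimates.  Includes Grubbs screening of
    assessor panels, replicate averaging and matrix assembly for seven-sensor
    e-tongue data, robust component selection (RCS) by leave-one-out
    cross-validation, outlier maps based on standardized residuals and score
    distances with three-way outlier classification, benchmark comparisons
    against multiple linear regression, classical SIMPLS and RBF-kernel least
    squares support vector machines, and a synthetic e-tongue data generator
    with planted outliers for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
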