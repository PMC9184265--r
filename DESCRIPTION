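Package: bonedca
Title: Decision-Curve Evaluation of Selective Bone-Scan Staging Strategies
    in Prostate Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: External validation and decision-curve comparison of selective
    bone-scan staging strategies for newly diagnosed prostate cancer.
    Implements eleven published risk models and guideline rules as a model
    registry, a synthetic registry-cohort generator with a latent
    scan-positivity model and missing-at-random masking, multiple imputation
    by chained equations with Rubin's-rules pooling, calibration (slope and
    calibration-in-the-large) and discrimination (AUC) metrics, and
    net-benefit decision curves over a preference-ratio /
    number-willing-to-test axis with an optimal-strategy map.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
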