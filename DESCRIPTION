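Package: schrothagree
Title: Rater Reliability Analysis for Schroth Curve-Type Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how reliably clinicians classify Schroth
    scoliosis curve types (3c, 3cp, 4c, 4cp). Provides a deterministic
    rule engine for the postural classification algorithm with a full
    decision trace; multi-rater chance-corrected agreement statistics
    (Gwet's AC1 and its weighted generalization with an arbitrary
    partial-credit weight matrix) with missing-rating support and
    jackknife confidence intervals; Fisher-transformation pooling of
    coefficients, critical-value benchmarking and precision criteria;
    and a generative simulator of two-occasion multi-rater rating
    studies for validating the whole pipeline without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
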