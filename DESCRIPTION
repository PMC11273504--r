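Package: rfitrial
Title: Residual Feed Intake Evaluation for Beef Heifer Performance Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing individual-intake performance tests of
    growing beef cattle. Computes average daily gain by regression and by
    endpoint difference, metabolic midweight, and residual feed intake
    (RFI) from four alternative expected-intake regressions with or
    without an ultrasound backfat covariate; classifies animals into
    low/medium/high efficiency classes within contemporary group;
    evaluates shortened test durations by regressing full-test values on
    truncated-test values; and quantifies classification agreement with
    weighted Cohen's kappa. Includes a seeded simulator of multi-group
    feed trials so the whole pipeline can be exercised and validated
    without proprietary trial data, plus data-editing (QC) filters for
    age windows, incomplete feed records, and contemporary-group intake
    outliers.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
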