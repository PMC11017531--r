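Package: prevcal
Title: Prevalence-Calibrated Performance Metrics for Binary Classifier Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating binary classification models under
    class-imbalance and prevalence shift. Re-parameterises a confusion
    matrix as (sensitivity, specificity, prevalence, N), reconstructs the
    derived confusion matrix at any target prevalence, and computes
    prevalence-calibrated ("balanced") versions of standard validation
    metrics, including the balanced Matthews correlation coefficient.
    Provides prevalence-sweep curves, synthetic validation scenarios, and a
    comparison report that flags misleading raw-metric variation when two
    test sets differ in prevalence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
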