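Package: frmakit
Title: Frozen-Parameter Robust Multi-Array Preprocessing for Expression
    Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to train frozen parameter vectors (a reference quantile
    distribution, robust probe effects, within- and between-batch probe
    variances, and probeset-level summaries) from a batch-labelled
    probe-level training set, and to preprocess single arrays or small
    batches of arrays against those frozen vectors so that expression
    estimates do not depend on which other arrays are processed alongside.
    Includes normal-exponential background correction, quantile
    normalization to a fixed reference, a median-polish RMA baseline,
    per-probe batch-effect F diagnostics, a latin-square spike-in
    simulator, and accuracy/precision evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
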