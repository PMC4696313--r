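Package: entrovar
Title: Differential Shannon Entropy, Coefficient of Variation and
    Expression for Case/Control Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Per-feature differential-variability analysis of two
    row-matched expression matrices. Computes normalized Shannon entropy,
    coefficient of variation and mean for each feature under each
    condition, together with their absolute differences (DSE, DCV, DE),
    and attaches raw and multiplicity-adjusted p-values via a pooled
    permutation test (DSE), the Fligner-Killeen homogeneity-of-variances
    test on log-transformed data (DCV) and the Welch two-sample t-test
    (DE).  Includes delimited-file readers and writers, a command-line
    entry point, and a deterministic synthetic-data generator with known
    differential-variability structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
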