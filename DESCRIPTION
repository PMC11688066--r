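Package: plsinvar
Title: Cancer-Specific Normal-Invariant Gene Selection via Modified
    Partial Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Selects genes that discriminate two tumour types while
    remaining invariant across the matched normal tissues, using a
    modified partial-least-squares procedure: ordinary PLS-DA weights on
    tumour samples are intersected with a normal-sample filter built from
    the covariance direction v = X'Y, either through uniform sampling of
    unit vectors orthogonal to v (squared-weight accumulation on the
    constrained hypersphere) or through the equivalent coefficient
    shortcut.  Includes a negative-binomial screen for dimension
    reduction, TPM conversion, a seeded synthetic count generator with
    planted gene classes, hierarchical cluster-purity validation, and
    Kaplan-Meier/log-rank survival screening of selected genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    mclust,
    stats,
    survival,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
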