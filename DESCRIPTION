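Package: hdmr2
Title: Second-Order HDMR Classification and Differential Co-Expression Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Glass-box binary classification of (log-)expression data by a
    second-order high dimensional model representation (HDMR) of the
    log-likelihood ratio. Per-gene and per-gene-pair regularized Gaussian
    discriminant log-likelihood-ratio machines are screened by their
    between-class risks and combined with unit-norm weights (LAS-HDMR), or
    merged into per-feature risk-increasing/decreasing blocks (LABS-HDMR).
    Includes the multiple-test-mixing (MTM) hypothesis test for detecting
    class-differential pairwise co-expression (per-class Pearson tests
    combined by Fisher's method, a covariance-equality likelihood-ratio test,
    and a union-bound combination with Benjamini-Hochberg FDR control), a
    two-sample Gaussian likelihood-ratio gene ranking with probe collapsing,
    a block-covariance synthetic expression simulator with marker and
    non-marker feature types, and ROC/AUC experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
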