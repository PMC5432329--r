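Package: scmixture
Title: Model-Based Clustering and Rare Subpopulation Detection for
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-stage model-based analysis of single-cell RNA-seq
    expression matrices: depth-based cell filtering and high-variance gene
    panel selection, followed by constrained-covariance Gaussian mixture
    clustering fitted by expectation-maximization with Bayesian information
    criterion model selection. Includes detection of cluster-specific
    suppressed-gene signatures, pooled Mann-Whitney and Kolmogorov-Smirnov
    two-sample checks, a sampling-based mixture goodness-of-fit check, and a
    seeded synthetic scRNA-seq generator (Poisson counts over log-normal
    rates with dropout) that emulates a deeply sequenced two-condition
    single-cell experiment for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
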