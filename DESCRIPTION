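Package: robsam
Title: Robust Significance Analysis of Microarrays via Minimum Beta-Divergence Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Significance Analysis of Microarrays (SAM) for two or more
    experimental conditions, robustified against outlying expression values.
    Per-gene, per-condition means and variances are estimated by the iterative
    minimum beta-divergence (density power divergence) method; observations are
    classified as outliers by an exponential beta-weight function with a global
    cutoff, and the SAM d-statistic is computed from robust estimates only for
    the gene-condition groups that are actually contaminated.  Includes the
    classical permutation machinery (fuzz constant s0, expected order
    statistics, Delta-thresholding, permutation FDR), a seeded synthetic-data
    generator with controlled outlier injection, ranking-based evaluation
    (confusion-matrix rates, ROC, AUC, partial AUC), replication harnesses for
    simulation studies, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
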