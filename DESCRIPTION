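Package: toxrank
Title: Organ-Specific Toxicity Gene Prioritization by Rank Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a protocol for prioritizing genes associated with
    organ-specific drug toxicity from multi-compound toxicogenomics panels.
    Per-compound time-course differential expression is screened with a
    two-step polynomial regression (global F-test at FDR, then backward
    stepwise coefficient selection), converted into extended partial
    rankings of a fixed gene universe, and aggregated across compounds with
    six methods: mean rank, number-of-compounds, robust rank aggregation by
    beta order statistics (RRA), joint order-statistic probabilities
    (STUART), Bayesian iterative rank reweighting (BIRRA), and the median of
    the five (AR). Literature-derived positive gene sets are built by
    gene-abstract co-occurrence testing with Fisher's exact test, and
    rankings are evaluated by ROC/AUC and compared across model systems by
    Spearman correlation and rank combination scores. A synthetic-data
    module generates expression panels with planted toxicity-responsive
    genes and matching literature annotations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
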