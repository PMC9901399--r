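Package: dcoex
Title: Differential Co-Expression Network Analysis over Predefined
    Interaction Networks
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tests whether the correlation of molecule pairs (for example
    miRNA-isoform/mRNA target pairs) differs between two sample groups,
    using the Fisher z-transformation test for equality of Pearson or
    Spearman correlations with analytic and label-permutation p-values.
    Supports a predefined directed interaction network or exhaustive
    all-pairs testing, source-molecule aggregation via hypergeometric
    overrepresentation and mean/median/quantile z-score summaries with
    permutation significance, multivariate-normal synthetic data
    generators and power-study drivers for validating the statistics,
    and helper computations for 5'-isomiR applications (RPM
    normalization, cumulative-expression filtering, AGO2 weighting and
    lost/gained target classification).
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
    pracma,
    withr,
    jsonlite
biocViews: GeneExpression, Network, StatisticalMethod, Regression
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
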