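Package: refrank
Title: Rank-Based Identification and Validation of Reference Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate reference (housekeeping) genes from
    collections of expression datasets by per-sample percentile ranking,
    per-dataset coefficient of variation of ranks, and occurrence-adjusted
    stability ratios; evaluates CV-threshold classifiers with ROC curves
    against a ground-truth housekeeping list; tests stability with
    rank-matched randomization and Kolmogorov-Smirnov comparisons; groups
    datasets by MeSH tree numbers for tissue-specific reference lists; and
    ranks RT-qPCR reference-gene candidates by relative-expression CV,
    geNorm M values and pairwise variation, and NormFinder-style
    intra/inter-group stability. Includes synthetic-data generators for
    GEO-like corpora with planted stable genes and simulated Cq tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
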