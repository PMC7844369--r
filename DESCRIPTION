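Package: methcall
Title: Differential DNA Methylation Calling from Two-Channel Array Intensities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for whole-genome differential DNA methylation
    analysis of two-channel methylation arrays, motivated by case-control
    studies of clopidogrel resistance in whole blood. Converts unmethylated
    (A) and methylated (B) probe intensities to beta-values with an offset
    pseudocount, applies background correction, optional probe scaling,
    quantile normalization and the logit (M-value) transform, tests each
    probe with the Wilcoxon rank-sum test, adjusts p-values by
    Benjamini-Hochberg, and calls hyper- and hypomethylated positions by
    p-value and delta-beta thresholds. Includes CpG-island
    shore/shelf/open-sea and gene-region (TSS200/TSS1500/5'UTR/1st
    exon/body/3'UTR) annotation, hypergeometric gene-set
    over-representation from GMT files, a seeded synthetic-data generator
    emulating an 850K-style array with planted effects and ground truth,
    and targeted validation statistics: pooled-variance t-tests from
    summary statistics, 2x2 chi-squared tests, logistic regression odds
    ratios, and delta-delta-Ct relative expression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
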