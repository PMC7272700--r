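Package: cachexnet
Title: Integrative miRNA-mRNA Analysis of Muscle-Wasting Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative analysis toolkit for paired bulk mRNA and miRNA
    count data from two-group (control vs case) designs, motivated by studies
    of skeletal-muscle wasting in cancer cachexia. Provides median-of-ratios
    normalization, CPM/RPKM conversion, a negative-binomial Wald test for
    differential expression with Benjamini-Hochberg correction, expression
    stability analysis via the percent coefficient of variation of per-sample
    fold changes, k-means clustering of standardized expression, sample PCA
    and near-control subgroup detection, Pscan-style position-weight-matrix
    promoter motif enrichment against CpG-matched backgrounds, hypergeometric
    gene-set over-representation, anti-correlation-filtered miRNA-target
    networks with Jaccard-weighted miRNA overlap edges, and box-counting
    fractal dimension plus stained-area quantification for histology images.
    A synthetic-data generator with planted ground truth makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    igraph,
    Biostrings,
    png,
    tiff,
    EBImage,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
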