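Package: omicsconcord
Title: Integrative Transcriptome-Proteome Concordance Analysis of
    Multi-Group Gonad Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating bulk RNA-seq and label-free proteomic
    data from factorial (sex by origin) designs, as used in studies of
    reproductive dysfunction in cultured flatfish gonads. Implements
    per-layer differential abundance (a negative-binomial Wald test for
    counts and an empirical-Bayes moderated t-test for log intensities),
    construction of mapped gene-protein pairs per contrast, a six-category
    regulatory-pattern classification (concordant up/down, discordant,
    RNA- or protein-exclusive, non-significant), cross-layer log2
    fold-change correlation summaries, ranked-list and over-representation
    functional enrichment, per-CpG differential methylation with
    genomic-feature annotation, exploratory PCA and clustering views, a
    matched multi-omics synthetic-data generator with planted ground
    truth, and a single end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    MASS,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
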