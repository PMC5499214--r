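Package: varenrich
Title: Enrichment of Trait-Associated Variants in Regulatory Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing whether candidate enhancer regions are
    enriched with trait-associated variants from genome-wide association
    studies. Combines per-cohort GWAS summary statistics by
    inverse-variance meta-analysis, tests annotation sets with a
    size-matched permutation test and a weighted running-sum gene set
    enrichment statistic with core-SNP extraction, and provides the
    genomic-interval algebra (merge, gap-clustering, intersect, subtract,
    overlap matrices) needed to build and compare enhancer sets. A
    synthetic-data generator plants configurable enrichment so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    withr,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    GenomicRanges,
    IRanges,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
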