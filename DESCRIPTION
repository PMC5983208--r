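Package: methdmr
Title: Differential Methylation and DMR Discovery for HM450K Beta-Value
    Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for Illumina HM450K-style DNA
    methylation analysis of two-group cohorts: probe- and value-level
    quality filtering, per-probe differential methylation by a moderated
    t-statistic with empirical-Bayes variance shrinkage and
    Benjamini-Hochberg FDR, calling of differentially methylated regions
    (DMRs) from runs of consecutive same-direction probes, hotspot
    detection, genomic and chromatin-state annotation (CpG islands,
    promoters with Weber-style HCP/ICP/LCP CpG-density classes, bivalent
    H3K4me3/H3K27me3 domains), and integration with expression to
    nominate candidate repressed and ectopically expressed genes. A fully
    seeded synthetic-data generator produces manifests, beta-value
    cohorts with implanted DMRs, and expression tables so every step can
    be exercised and benchmarked without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    rlang,
    readr,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    broom,
    jsonlite,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
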