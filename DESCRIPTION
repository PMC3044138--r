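Package: tdmrscan
Title: Tissue-Specific Differential Methylation Analysis for Two-Channel
    Methylation Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for comparing DNA methylomes of two tissues
    measured on two-channel methylation microarrays.  Supports both
    Infinium-style CpG arrays (paired unmethylated/methylated probes, beta
    values and log(B/A) scores) and methylation-sensitive restriction-enzyme
    (HpaII/MspI) tiling arrays (log undigested/digested signal ratios).
    Provides cyclic-loess between-array normalization, empirical-Bayes
    moderated t tests with Benjamini-Hochberg false-discovery-rate control
    for site-level methylation calls, a sliding-window genome scan with a
    simulation-based empirical null that merges significant sites into
    differentially methylated regions, genomic-context annotation and Fisher
    enrichment tests (gene bodies, promoters, exons, CpG islands, GO terms),
    cubic smoothing-spline regression of gene expression on promoter and
    gene-body methylation with trace-of-smoother-matrix F tests, promoter
    CpG observed/expected stratification, and a fully seeded synthetic-data
    generator that emulates the statistical structure of a placental
    chorionic-villus versus maternal-blood-cell methylome study so that
    every stage can be exercised and benchmarked without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite,
    optparse
Config/testthat/edition: 3
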