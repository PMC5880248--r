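Package: damidcall
Title: Peak Calling and Quantification for DamID-seq Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A toolkit for DamID-seq data analysis: partitions a genome into
    DpnI (GATC) restriction fragments, counts aligned reads fully contained in
    fragments, filters low-abundance fragments, normalizes with TMM scale
    factors and smooth quantile normalization, tests Dam-POI versus Dam-only
    differential methylation per fragment with trended, robust empirical-Bayes
    moderated t-statistics, merges fragments into peak regions with Simes
    combined p-values and Benjamini-Hochberg FDR control, produces scaled and
    Dam-subtracted coverage tracks, and computes qPCR-based DamID (qDamID)
    methylation percentages and enrichment scores. Includes a seeded
    negative-binomial simulator for end-to-end benchmarking of peak calls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    stats,
    utils,
    methods,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma,
    rtracklayer,
    GenomicRanges,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
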