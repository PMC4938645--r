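Package: methfrag
Title: Fragment-Level Comparative Analysis of RRBS Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of reduced representation
    bisulfite sequencing (RRBS) methylomes using MspI restriction fragments
    as the unit of analysis. Provides in-silico MspI digestion with size
    selection, per-fragment methylation calling from per-CpG bisulfite
    count tables with coverage filtering, two-group ANOVA calling of
    differentially methylated fragments under Bonferroni family-wise error
    control, logit-scale Gaussian mixture decomposition of methylation
    distributions, repeat-element and gene-model annotation summaries,
    genome-landscape density and enrichment statistics, and a synthetic
    two-group methylome generator with a planted-truth set for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    rtracklayer
Config/testthat/edition: 3
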