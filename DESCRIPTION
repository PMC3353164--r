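Package: vamir
Title: Small RNA Sequencing Analysis and miRNA Discovery for Amur Grape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing analysis toolkit built around
    miRNA discovery in Amur grape (Vitis amurensis Rupr.). Provides adapter
    trimming and read collapsing, exact genome mapping with annotation-track
    categorisation, mismatch-tolerant assignment of reads to known mature
    miRNAs, isomiR-style variant calling (miR-SNPs and miR-LDs), hairpin-based
    novel miRNA discovery with a built-in RNA secondary-structure engine and
    Meyers-style annotation criteria, Allen-rule miRNA target scanning with
    cleavage-site prediction, and a fully seeded synthetic-data generator with
    planted ground truth for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    stats,
    utils,
    methods,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
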