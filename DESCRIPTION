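Package: svarepeat
Title: Tandem Repeat Quantification and CpG Methylation Analysis for Noisy Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies hexanucleotide (and other short-motif) tandem repeat
    copy numbers in noisy long sequencing reads by wraparound affine-gap local
    alignment of each read against an unbounded tandem concatenation of the
    motif, classifies repeat interruptions (deletions, insertions,
    substitutions), and aggregates per-read calls to per-sample medians with
    interquartile ranges. Also provides hemizygous variant post-filtering
    (allele frequency, Phred quality and homopolymer-context rules), per-read
    CpG methylation call aggregation into filtered site- and region-level
    methylation frequencies with exact Mann-Whitney comparisons, rank-based
    concordance statistics against fragment-analysis sizing, and a synthetic
    read/methylation/fragment-size generator with ground-truth logs for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
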