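Package: maxcounts
Title: Exon Expression Summarization from Per-Base Read Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies exon expression from RNA-seq alignments as the maximum
    of per-base read coverage (maxcounts) alongside the conventional total
    read count (totcounts). Includes alignment post-processing (multiread and
    low-similarity filtering), FASTQ pre-processing (quality trimming, length
    filtering and re-mating of pairs), TMM, RPKM and full-quantile
    normalization, a diagnostic battery for length/GC bias, count
    concentration, replicate variance, spike-in accuracy and robustness to
    alignment filtering, and a synthetic-read simulator with non-uniform
    positional coverage and known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    ShortRead,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
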