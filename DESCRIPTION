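Package: replong
Title: Targeted Tandem Repeat Genotyping and Expansion Detection from Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for targeted tandem repeat analysis with long consensus
    reads: repeat discovery and annotation on a reference sequence, tiered
    target selection with a pluggable variability score, capture probe design
    with a genomic uniqueness screen, outward-shift rescue and GC-based probe
    replication, read preparation (adaptor trimming, window alignment,
    duplicate removal, yield accounting with soft-clip rescue), flank-anchored
    per-read allele calling with partial-read expansion lower bounds,
    X-linked pedigree segregation and control-population filtering, an
    expression deregulation ranking statistic, and a synthetic data generator
    that emulates a capture plus circular-consensus sequencing design for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
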