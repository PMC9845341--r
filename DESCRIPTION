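Package: svdense
Title: Density-Based Structural Variant Discovery from Long-Read Alignments
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects structural variants (insertions, deletions, tandem
    duplications, inversions and translocations) from long-read
    alignments. Per-read raw SV signals are extracted from CIGAR
    operations and split-read segment pairs, merged with a density-based
    clustering algorithm with size-adaptive windows, separated into
    alleles with an exact one-dimensional k-means, and refined to
    base-pair resolution with a partial order alignment consensus that is
    realigned to the local reference. Insertions longer than the reads
    are recovered by clip-anchored local assembly. Depth-adaptive
    filtering and ratio-based genotyping produce a standard VCF. A fully
    seeded simulator generates ground-truth SV sets, error-model reads
    and oracle alignments, and an evaluation module scores call sets
    against the truth (recall, precision, F1, breakpoint-shift profile).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Rsamtools,
    Biostrings,
    GenomicRanges,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
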