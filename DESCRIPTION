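Package: crisprScreen
Title: PAM Depletion Screen Analysis and CRISPR Locus Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing Type II CRISPR-Cas systems from
    sequencing data. Detects repeat-spacer arrays and anti-repeat
    (tracrRNA) candidates in locus sequences, analyses randomized-PAM
    (7N) depletion screens from interference or in vitro cleavage
    experiments (read QC, anchored PAM extraction, chi-square negative
    selection statistics, positional depletion profiles, IUPAC consensus
    calling), builds visualization-ready sequence-logo and hierarchical
    PAM-wheel matrices, reconstructs small-RNA species (mature crRNAs and
    tracrRNA products) from 5'/3' end coordinates, and simulates all of
    these data types under planted PAM-recognition models for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
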