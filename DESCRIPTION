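Package: CircPrimeR
Title: Back-Splice-Junction Spanning qPCR Assay Design for Circular RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design of circular-RNA-specific RT-qPCR primer pairs. Builds
    back-splice-junction (BSJ) centred template sequences from a reference
    genome and exon annotation (spliced or unspliced), masks common SNPs and
    stable secondary structures, enumerates junction-spanning primer pairs
    under nearest-neighbor melting-temperature and composition constraints,
    screens candidate pairs against a reference transcriptome with a
    mismatch-tolerance specificity matrix, applies amplicon folding rules,
    and selects the smallest passing amplicon per circRNA. Ships a
    deterministic synthetic-fixture generator so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
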