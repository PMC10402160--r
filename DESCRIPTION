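Package: spliceguard
Title: Splice-Junction Recognition and Spliced-Alignment Cleaning with a
    Dilated Residual Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognizes splice junctions from genomic sequence with a deep
    residual convolutional network operating on paired donor-acceptor windows
    (400nt around each site), trained with a focal-loss objective, and uses
    the resulting junction scores to remove spurious spliced alignments from
    RNA-seq alignment files. Includes native extraction of junctions from
    spliced alignments (CIGAR N operations) and from annotation, curation of
    positive and negative junction training sets, chromosome-held-out
    splitting, a cross-species pseudo-junction generator, intron-level
    precision/recall evaluation, and a seeded synthetic-data generator
    (toy genomes with planted canonical introns, decoy antisense GT-AG
    pairs, and simulated spliced alignments) so that the whole pipeline is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    graphics,
    tools,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
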