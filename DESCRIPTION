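Package: tipscan
Title: Detection, Validation and Dating of Transposable-Element Insertion Polymorphisms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for transposable-element insertion polymorphism (TIP)
    discovery across large short-read panels. Junction read pairs (one mate on a
    TE family consensus, the other uniquely anchored on the reference) are
    counted per 10-kb reference window and called with a two-pass 5/2 support
    threshold, yielding a presence/absence matrix across accessions. Companion
    procedures quantify per-window short-read mappability, validate calls with
    long reads via flank re-mapping, summarise insertion frequency spectra and
    gene proximity, and date LTR-retrotransposon insertions from LTR-LTR
    divergence under a molecular clock with cross-assembly ortholog
    classification. A ground-truth simulator generates reference genomes,
    accession panels with controlled insertion frequencies, and short/long
    reads for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    data.table,
    rtracklayer,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
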