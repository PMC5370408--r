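Package: aaRScreen
Title: Screening of Archaeal-Type tRNA Identities and Non-Canonical Class Ic
    Aminoacyl-tRNA Synthetases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects archaeal/eukaryal-type tRNA(Tyr) and tRNA(Trp) identity
    elements in bacterial contigs and annotates the non-canonical class Ic
    aminoacyl-tRNA synthetases that accompany them. Provides a deterministic
    cloverleaf parser with canonical numbering and identity-element typing,
    degenerate HIGH/KMSKS and iron-sulfur cysteine-spacing motif scanners,
    nearest-reference lineage classification of TyrRS/TrpRS proteins, domain
    architecture and recombination-breakpoint detection, operon-structure
    detection from GFF3 gene neighbourhoods, motif-anchored core trimming
    with neighbor-joining bootstrap phylogenies and clade assignment, and a
    permutation test of gene-tree congruence. A synthetic-data generator
    plants all of these signals in contigs with a fully known truth table so
    that the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
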