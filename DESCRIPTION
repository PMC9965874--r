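Package: mitoscreen
Title: Curation and Genome-Architecture Classification of Putative Mitoviruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens candidate RNA-virus contigs for mitovirus-like genomes and
    classifies their coding architecture. Deduces open reading frames under
    alternative (mitochondrial and plastid-like) genetic codes, profiles
    in-frame UGA/UGG tryptophan codon usage and genome AU content, detects
    ambigrammatic reverse-strand ORFs, applies a reproducible curation filter
    chain (single long ORF, ordered RNA-dependent RNA polymerase motif
    presence, global-alignment identity deduplication), and computes
    midpoint-rooting and clade branch-length diagnostics on phylogenetic
    trees. Includes a calibrated synthetic-genome generator that provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    phytools,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
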