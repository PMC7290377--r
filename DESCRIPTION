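Package: satkit
Title: Characterization of Satellite DNA Repeats, Higher-Order Structure,
    and Transposable-Element Associations
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Detects tandem-repeat periodicity in satellite DNA, extracts
    monomers from multimeric clones and builds majority-rule consensus
    sequences, decomposes monomers into higher-order-repeat (HOR) subunits,
    scores intra- and inter-species monomer diversity with neighbor-joining
    dendrograms, finds satellite-like sequences genome-wide by seed-and-extend
    local alignment, detects target-site duplications around transposable
    elements that captured satellite units, annotates and classifies satellite
    distribution along pseudochromosomes, and estimates copy numbers from
    read-cluster genome proportions. Ships a seeded synthetic satellite-genome
    generator with machine-readable planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
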