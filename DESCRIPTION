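Package: MetaSSU
Title: Parallel 16S rRNA Profiling of Shotgun Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained pipeline for taxonomic profiling of shotgun
    metagenomic reads via the small-subunit (16S) rRNA gene. Detects 16S
    fragments with a profile hidden Markov model scanned by a local Viterbi
    algorithm on both strands, maps extracted fragments to an annotated 16S
    reference database with a chunk-parallel seed-and-extend nucleotide
    aligner whose merged output is identical to serial execution, assigns
    Greengenes-style taxonomic lineages by best hit, and compares multiple
    samples on one consensus taxonomy tree with per-sample normalized
    proportions rendered as bar charts. Includes a synthetic community
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    xml2,
    optparse
Config/testthat/edition: 3
biocViews: Metagenomics, Microbiome, Sequencing, Alignment
RoxygenNote: 7.3.3
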