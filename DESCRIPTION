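Package: rollcirc
Title: Reference-Free Profiling of Extrachromosomal Circular DNA from
    Rolling-Circle Concatemer Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects extrachromosomal circular DNA (eccDNA) in high-accuracy
    long reads produced by rolling-circle amplification. Each read is scanned
    for tandem concatemer structure, the monomer period and number of
    amplification rounds are estimated, and a majority-vote consensus of the
    circular unit is reconstructed; only reads with more than one round of
    concatenation are retained as eccDNA evidence. Downstream layers map the
    monomers to genome, transposable-element (TE) and coding-sequence
    databases, classify origins (full/partial TE, single-event, chromosome
    window), build normalized per-window and per-TE abundance tables, cluster
    monomers into a non-redundant set, and provide the inferential layer
    (TE-superfamily enrichment against genomic composition, group
    comparisons, epigenetic-track and fold-change correlations, inverted
    repeat overlap counts, and centromeric partition tests). A seeded
    synthetic-data module generates toy genomes, circle populations and
    concatemer reads with ground truth so the whole pipeline is testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
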