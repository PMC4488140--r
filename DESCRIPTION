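Package: ssrmine
Title: Microsatellite Mining, Marker Design and In Silico Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A genome-to-marker toolkit for simple sequence repeats (SSRs).
    Mines perfect di- to hexanucleotide microsatellites from DNA sequence
    sets, classifies loci by repeat class, tract length and base
    composition, designs and deduplicates flanking PCR primer pairs,
    evaluates markers by electronic PCR (physical mapping, cross-taxon
    transferability, amplicon-size polymorphism), screens flanking regions
    for transposable-element and miRNA association, and computes marker
    potential statistics (allele counts, polymorphism information content).
    Includes a seeded synthetic-fixture generator that plants repeats,
    transposon fragments and pre-miRNA hairpins into simulated genomes with
    exact truth tables, so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
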