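Package: FlavoScreen
Title: Screening Human Gut MAG Protein Catalogs for Flavonoid-Modifying Enzymes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An in silico screen for flavonoid-modifying enzymes across
    metagenome-assembled genome (MAG) protein catalogs in the UHGP layout
    (representative protein FASTA, redundancy membership table, genome
    metadata with GTDB lineages). Provides a curated registry of
    characterized flavonoid-modifying enzyme queries with length-stratified
    e-value regimes, local protein homology search and a reader for BLAST
    tabular hits, percent-identity/coverage threshold filtering with
    best-bitscore deduplication, redundancy-aware occurrence counting
    ("Freq"), multi-gene pathway co-occurrence calling per genome, species
    prevalence and abundance statistics, greedy CD-hit-style sequence
    clustering, and a synthetic catalog simulator with implanted homologs
    and a machine-readable truth table for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Metagenomics, Microbiome, SequenceMatching, Software
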