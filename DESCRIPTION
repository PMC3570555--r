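Package: msatselect
Title: Microsatellite Marker Selection from Pyrosequencing Reads
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-sequencing selection of microsatellite (SSR) marker
    candidates from single-end pyrosequencing reads. Provides MID barcode
    demultiplexing, Lucy-style sliding-window quality trimming with high- and
    low-stringency presets, detection of perfect di- to hexanucleotide tandem
    repeats, all-against-all identity clustering of repeat-flanking regions
    into contigs with majority-rule consensus building and elimination of
    partial homologs, screening against a repetitive-element library, and
    constraint-based PCR primer design with a nearest-neighbor melting
    temperature model. A deterministic 454-style read simulator with planted
    repeats, planted repetitive elements, 3' quality decay and homopolymer
    indel errors supplies ground truth for every stage, and a two-track
    pipeline driver (stringent-QC singletons and relaxed-QC contig
    consensuses) produces ranked primer pairs and a summary ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
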