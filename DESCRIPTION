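Package: aviDNA
Title: Avian eDNA Metabarcoding with Universal 12S Primers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for avian environmental-DNA (eDNA) metabarcoding built
    around the MiBird-U universal 12S rRNA primer set. Implements in-silico
    primer evaluation (wobble-aware mismatch counting, positional base
    composition, GC content, nearest-neighbour melting temperature),
    in-silico PCR with amplicon-insert extraction and edit-distance based
    taxonomic-resolution analysis, the amplicon read-processing pipeline
    (quality tail trimming, pair merging, length/ambiguity filtering,
    primer removal, two-tier dereplication), BLAST-style taxonomic
    assignment with reliability and ratio scores, per-sample detection
    tables with negative-control screening, and a deterministic simulator
    of reference panels and multi-sample surveys for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: Metagenomics, Microbiome, SequenceMatching, Preprocessing
RoxygenNote: 7.3.3
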