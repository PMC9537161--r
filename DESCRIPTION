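Package: MitoLongCall
Title: Heteroplasmy Calling and Cut-Site Demultiplexing for Cas9-Enriched
    Full-Length Mitochondrial Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Informatics pipeline for multiplexed, Cas9-enriched, full-length
    mitochondrial genome sequencing with nanopore long reads.  Reads are
    demultiplexed by the genomic position of their Cas9 cut-site, remapped
    against doubled and masked per-cut-site references so that circular
    molecules align in one piece, and heteroplasmic variant allele fractions
    are estimated by maximum likelihood with Fisher scoring under a
    quality-stratified error model.  Long deletions are detected from
    per-read deletion intervals, clustered and quantified jointly with the
    intact molecule; single-nucleotide variants can be phased directly from
    a per-read by per-position view matrix.  A synthetic-data simulator
    generates reads, truth tables and ideal PAF/SAM alignments so the whole
    pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    Biostrings,
    S4Vectors,
    Rsamtools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
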