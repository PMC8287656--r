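Package: mitocomp
Title: Comparative Analysis of Fungal Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Mitocomp", "Developers", email = "mitocomp@example.org",
           role = c("aut", "cre"))
Description: Toolkit for desk-scale comparative mitogenomics of fungi:
    GenBank flat-file ingestion with exon/intron-aware CDS extraction,
    base-composition and strand-skew statistics, per-gene Kimura
    2-parameter distances with a neighbor-joining utility, Nei-Gojobori
    (1986) Ka/Ks estimation with positive-selection flagging, group-I
    intron position-class (Pcl) mapping against a reference coding
    sequence, circular gene-order canonicalization and breakpoint
    analysis, repeat and tandem-repeat accounting, cohort summary tables
    with size-intron correlation, and a fully deterministic synthetic
    mitogenome generator with a ground-truth manifest so that every
    pipeline stage is testable without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    optparse
Config/testthat/edition: 3
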