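Package: silkmotifs
Title: Spidroin Repeat Motif Catalogs, Cassette Detection, and Silk-Gland
    Expression Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing the repetitive architecture of spider
    silk proteins (spidroins). Screens translated gene models for spidroin
    candidates by local homology to curated N-/C-terminal domain libraries
    and signature motifs, discovers repetitive motif variants (4-41 residues)
    in spidroin cores, paints motif occurrences back onto sequences, detects
    higher-order cassettes (ordered runs of 2-6 adjacent motifs), computes
    cross-species motif and cassette sharing summaries, and profiles relative
    silk-gland transcript abundance from qPCR cycle thresholds with the
    2^-ddCt method. Ships a synthetic spidroin generator with full ground
    truth so every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: Proteomics, SequenceMatching, GeneExpression
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'sequence_io.R'
    'screen.R'
    'motifs.R'
    'cassettes.R'
    'sharing.R'
    'qpcr.R'
    'simulate.R'
    'reports.R'
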