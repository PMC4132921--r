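Package: chemomine
Title: Mining, Phylogenetics, Site-Level Selection and Repeat-Landscape
    Analysis of Chemosensory Receptor Gene Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, fully testable re-implementation of a
    chemosensory gene-repertoire study pipeline: a synthetic-genome
    generator planting clustered intronless GPCR genes with known
    site-class dN/dS truth, pseudogene and allelic confounders, and a
    configurable transposable-element landscape; a deterministic seeded
    translated homology search with ORF repair and allele collapsing; a
    progressive protein aligner with neighbor-joining trees, bootstrap
    branch support and reciprocal-outgroup family assignment;
    sequence-logo conservation and cross-family motif comparison with
    hydropathy-based transmembrane annotation; per-codon selection
    inference by SLAC counting and FEL likelihood-ratio tests with a
    two-method consensus; and multi-scale class-I transposable-element
    density statistics around gene clusters.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    ape,
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
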