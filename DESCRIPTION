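Package: vitisugar
Title: Sugar-Transporter Gene Family Classification, Promoter
    Cis-Element Scanning and Macroarray Expression Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated pipeline for plant sugar-transporter gene
    families, modelled on the grapevine (Vitis vinifera) sucrose and
    monosaccharide transporter analysis workflow. Provides
    similarity-based subfamily assignment of transporter proteins
    against a labelled reference panel using global affine-gap
    alignment and shorter-sequence percent similarity, a
    neighbor-joining distance tree of the family, extraction of 2 kb
    promoter regions with upstream-ORF truncation, IUPAC-degenerate
    cis-regulatory element scanning with common/unique/
    family-restricted/sugar-responsive classification, and a
    macroarray quantification pipeline (background subtraction,
    negative-control presence calls, four-reference-gene
    normalization, replicate aggregation and per-organ
    high-expression calls). Seeded synthetic-data generators emit
    promoter sets with planted motifs, membrane spot tables with
    known expression matrices, and diverged protein families with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    rtracklayer,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'alignment.R'
    'assign.R'
    'classify.R'
    'io.R'
    'macroarray.R'
    'motifs.R'
    'njtree.R'
    'promoter.R'
    'simulate.R'
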