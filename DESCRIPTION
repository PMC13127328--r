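Package: spatialTCR
Title: Spatial T Cell Receptor Repertoire Mapping from Targeted In Situ Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spatially resolved T cell receptor (TCR) repertoire
    analysis from targeted in situ sequencing (Xenium-style) data. Implements
    design of gene-discriminating 30-mer padlock-probe targets for TCR V/J/C
    genes, rule-based single-cell TCRVb/Va clonotype calling from decoded
    transcript tables, hexagon-binned TCR density and diversity maps,
    permutation-based neighbourhood enrichment on fixed-radius spatial graphs,
    repertoire diversity statistics (Gini index, abundance-based Jaccard), and
    a seeded synthetic-tissue generator with known clonal ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    data.table,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite,
    vegan
Suggests:
    testthat (>= 3.0.0),
    arrow,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
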