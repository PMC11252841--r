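Package: scRadial
Title: Scriptable Exploration of Single-Cell RNA-Seq Data with Radial
    Expression Charts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A scriptable library for exploratory analysis of single-cell
    RNA-seq count data, with a focus on bacterial scRNA-seq. Imports the
    three-file dataset model (count matrix, gene annotation, phenotypic
    data) with strict naming conventions, provides a chainable gene-filter
    engine (top expression, top differential expression, genomic region,
    metadata category, gene group, custom sets), metacell aggregation by
    mean or median, log2 fold-change between cells and metacells,
    PCA/UMAP/precomputed low-dimensional embeddings with axis selection,
    metadata-linked cell and gene coloring, and deterministic radial
    expression-chart, fold-change chart and scatter-plot export to SVG and
    PNG. Includes a command-line interface and a synthetic dataset
    generator for reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    readxl,
    uwot,
    rtracklayer,
    S4Vectors,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    xml2,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
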