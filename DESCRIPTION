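Package: atlascast
Title: Projection of Single-Cell Transcriptomes onto Bulk Reference Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Projects query single-cell RNA-seq profiles onto bulk reference
    expression atlases without batch correction. Reference atlases are built by
    within-sample rank transformation, Hellinger-distance discriminant gene
    selection and gene-centred principal component analysis. Query cells are
    prepared either by bootstrap pseudo-bulk aggregation of clusters or by
    adaptive graph-diffusion imputation (distance scaling beyond the nearest
    neighbour, adaptive Gaussian kernels, Fuzzy Jaccard symmetrisation and a
    Laplace-Beltrami normalised Markov operator), then mapped into atlas
    principal-component coordinates with optional diffusion-map refinement.
    Continuum cell identity is scored by weighted restricted least squares
    against reference cell-type predictors. Includes a synthetic data
    generator, projection-quality metrics and a composite pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    cluster,
    mclust,
    quadprog,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
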