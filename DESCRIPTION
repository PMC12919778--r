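Package: featurelens
Title: Batch-Effect and Bias Inspection for Learned Image Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Model-agnostic tools for detecting batch effects, bias and
    overfitting in learned image embeddings, with whole-slide-image tiles
    as the motivating case. Provides linear probing of sensitive or
    prognostic variables with bootstrap confidence intervals and Cohen's
    kappa, two-dimensional projection under a pluggable reducer contract
    with structure-preservation scoring (silhouette, adjusted Rand index,
    k-nearest-neighbour preservation, correlation of pairwise distances),
    covariate-balanced and patient-disjoint data sampling, tile-grid
    tessellation with whitespace filtering, training-loop inspection
    hooks, a self-contained interactive HTML report, and a seeded
    synthetic-embedding generator with controllable batch-effect
    magnitude for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    data.table,
    arrow,
    withr,
    png
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    cluster,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'EmbeddingSet.R'
    'projector.R'
    'scores.R'
    'report.R'
    'cli.R'
    'featurelens-package.R'
    'probe.R'
    'hooks.R'
    'io.R'
    'sampling.R'
    'synthetic.R'
    'utils.R'
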