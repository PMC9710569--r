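Package: sparcler
Title: Iterative Maximum-Likelihood Assignment of Dangling Transcripts to
    Cells in Multiplexed FISH Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reassigns "dangling" mRNA spots (transcripts detected outside
    cell segmentation boundaries in MERFISH/smFISH-style images) to
    neighboring cells by an iterative maximum-likelihood procedure:
    cluster the cell-by-gene count matrix, learn per-cluster multivariate
    Gaussian moments, build a distance-weighted circular mock cell around
    each dangling spot, call its most likely cluster and assign it to the
    nearest cell of that cluster. Includes a ground-truth synthetic
    field-of-view simulator, graph-based and Dirichlet process mixture
    model clustering, and covariance-based evaluation statistics (Gramian
    and cross-covariance cluster matrices, Box's M test, Frobenius
    distance, Loewner ordering, Pearson block correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    igraph,
    mclust,
    withr,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'simulate.R'
    'clustering.R'
    'dpmm.R'
    'assignment.R'
    'driver.R'
    'evaluate.R'
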