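Package: tsee
Title: Time Series Elastic Embedding for Single-Cell Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear dimensionality reduction for time series single-cell
    RNA-seq data. Extends elastic embedding with a temporal repulsive term
    that penalizes placing cells collected at distant experimental time
    stages close together in the low-dimensional map, diluting batch-like
    distortion across collection times. Includes the companion preprocessing
    pipeline (variable-gene selection, global min-max scaling, PCA), neighbor
    purity metrics for embeddings (in-group proportion and its time-adjacent
    relaxation, weighted means, a misplaced-cell diagnostic, stage-centroid
    linkage trees), a synthetic time-course generator with known latent
    structure, and readers/writers plus a command-line interface for dense
    and MatrixMarket expression matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
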