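Package: recodetools
Title: Resolution of the Curse of Dimensionality for Single-Cell Count Data
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Noise reduction for high-dimensional single-cell sequencing count
    matrices. Implements noise variance-stabilizing normalization (NVSN), the
    eigenvalue-modification denoising transform acting in a low-dimensional
    essential space (with an accuracy-improved sparse eigenvector variant), a
    batch-integration extension that applies any batch corrector inside the
    essential space, fast truncated spectral learning and downsampling
    learning for large datasets, adapters for single-cell Hi-C contact maps
    and spatial transcriptomics, the evaluation statistics used to benchmark
    such methods (dropout rate, cross-batch relative error, Welch's t, LISI,
    silhouette, variance ratios), and seeded synthetic-data generators based
    on the random-sampling noise model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    cluster,
    methods,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
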