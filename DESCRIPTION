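Package: mastertime
Title: Manifold Alignment of Single-Cell Multi-Omic Modalities via Master Time
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns single-cell data modalities (transcriptome, DNA methylation,
    chromatin accessibility, histone marks) measured on different cells of the
    same biological process. Each modality's one-dimensional pseudotime is
    inferred with a Bayesian Gaussian process latent variable model (variational
    inference with inducing inputs), warped onto a common uniform "master time"
    by monotone quantile alignment, and the generative model is then used to
    infer corresponding measurements across modalities, enabling cross-modality
    correlation of features at single-cell resolution. Includes the
    feature-engineering steps for aggregated epigenomic signatures, a seeded
    synthetic-data generator with known ground truth, decoupling statistics,
    shared-latent models for simultaneously measured modalities, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
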