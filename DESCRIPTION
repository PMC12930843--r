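Package: atacAnno
Title: Two-Stage scATAC-seq Cell-Type Annotation with Graph Domain Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates cells in single-cell ATAC-seq query datasets by
    transferring labels from an annotated reference profiled on a different
    platform. Stage one learns cell embeddings either from peak DNA-sequence
    features, by training a feedforward network to predict per-cell
    chromatin accessibility and reading the cell embeddings off the
    output-layer weight columns, or by the standard latent semantic indexing
    route (binarize, TF-IDF, truncated SVD). Stage two builds k-nearest
    neighbour cell graphs for both domains and trains weight-shared,
    asymmetric-depth graph convolutional networks with an adversarial domain
    discriminator behind a gradient reversal layer, so that reference labels
    transfer across batch effects. Includes a synthetic-data generator with
    known cell types, planted sequence motifs and controllable batch shifts
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
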