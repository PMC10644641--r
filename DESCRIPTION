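Package: mdwgan
Title: Multi-Discriminator Wasserstein GAN for Gene Expression Data Augmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Augments bulk and single-cell gene expression cohorts with a
    conditional Wasserstein GAN with gradient penalty whose critic is trained
    on three views of the data: the raw training matrix and two variants
    smoothed by a parameter-free linear graph convolution over K-nearest
    neighbour sample graphs (Euclidean and cosine). Includes expression matrix
    input/output with log/z-score normalization, a seeded synthetic cohort
    generator with block gene-gene correlation, and an evaluation suite
    covering gene-correlation similarity, confusion-matrix metrics, and
    train-on-synthetic/test-on-real classification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    randomForest,
    class
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
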