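Package: spotnb
Title: Probabilistic Prediction of Spot-Level Gene Expression from H&E
    Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts per-spot gene-expression distributions from
    haematoxylin-and-eosin (H&E) image tiles in spot-based spatial
    transcriptomics. A negative-binomial regression head maps tile
    feature embeddings to per-gene (r, p) distribution parameters and is
    trained by minimising the negative-binomial negative log-likelihood.
    Seeded model ensembles decompose predictive uncertainty into
    aleatoric and epistemic components via the law of total variance.
    Also provides spot-centred tiling with stain normalisation and
    tissue-coverage quality control, high/low expression classification
    with elastic-net logistic regression, LIME attribution over nucleus
    segments, spatial evaluation metrics (Pearson correlation, Moran's
    I, AUC, and a geometric spatial-pattern intersection-over-union),
    and a synthetic-slide generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    EBImage,
    glmnet,
    pROC,
    png,
    tiff,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse,
    withr
Config/testthat/edition: 3
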