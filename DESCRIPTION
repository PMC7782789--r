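Package: xmodal
Title: Cross-Modal Autoencoders for Unpaired Single-Cell Data Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates and translates between unpaired single-cell data
    modalities with very different structures, such as expression vectors and
    3D chromatin images, by embedding each modality into a shared latent space
    with per-modality autoencoders and aligning the latent distributions
    adversarially. Includes optional prior-knowledge losses (conditioned
    discriminators, latent classifiers, anchor pairs), cross-modal translation
    by composing encoders and decoders, evaluation metrics (latent
    cluster-assignment accuracy, k-nearest-neighbour matching accuracy,
    classifier-transfer ROC, co-association matrices), a 3D radial
    chromatin-density feature pipeline over nested erosion shells, and a
    synthetic coupled-multimodal benchmark generator so the whole pipeline is
    exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    tiff,
    randomForest,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust
Config/testthat/edition: 3
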