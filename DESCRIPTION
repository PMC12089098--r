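Package: brainalign
Title: Representational Alignment Between Network Models and Brain Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Quantifies how well the internal representations of artificial
    network models align with multi-subject brain responses to a shared
    stimulus set. Implements representational similarity analysis (RSA) on
    representational dissimilarity matrices with subject averaging, noise
    ceilings and group significance; weighted RSA; volumetric searchlight RSA;
    linear and ridge voxelwise encoding models with cross-validation; stacked
    encoding over multiple feature spaces; voxelwise-encoding RSA (veRSA);
    unique/shared variance partitioning and structured (nested) variance
    partitioning; centered kernel alignment; and distributional comparisons
    (Jensen-Shannon divergence, 1-D Wasserstein distance). Includes a model
    taxonomy registry for attribute-based model selection, a framework-
    agnostic layer-activation extractor with PCA and sparse-random-projection
    reduction, publication-style plots, a reproducible run pipeline, and a
    synthetic dataset generator that emulates shared latent structure across
    model layers and subjects so every analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    pracma,
    rlang,
    RNifti,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
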