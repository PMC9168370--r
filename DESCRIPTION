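Package: radstab
Title: Perturbation Robustness Screening and Model Benchmarking for
    Radiomics Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how stable quantitative image features are
    under controlled image perturbations, and for high-throughput
    benchmarking of feature-selector and classifier combinations on the
    surviving features. Includes a synthetic CT tumour-phantom cohort
    generator, an image standardization chain (resegmentation, adaptive
    windowing, denoising, histogram equalization, slice selection,
    cropping), an 851-feature handcrafted radiomics extractor
    (first-order, shape, GLCM, GLRLM, GLSZM, GLDM, NGTDM families with
    single-level wavelet filtration), slice-thickness, rotation and
    segmentation perturbations scored by the intraclass correlation
    coefficient ICC(2,1), a four-stage feature-selection cascade with
    thirteen filter selectors, a twelve-classifier cross-validated
    benchmark scored by AUC and relative standard deviation, and
    Kaplan-Meier, log-rank and Cox survival follow-through.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    igraph,
    survival,
    MASS,
    rpart,
    randomForest,
    e1071,
    kernlab,
    nnet,
    xgboost,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
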