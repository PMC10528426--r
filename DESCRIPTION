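Package: retinomics
Title: Explainable Radiomic Screening of Age-Related Macular Degeneration
    on Ultra-Widefield Fundus Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end radiomic screening pipeline for age-related macular
    degeneration (AMD) on ultra-widefield fundus retinographs: automatic
    macula localisation with a fixed-radius circular region-of-interest
    contract, IBSI-style 2D radiomic feature extraction (intensity,
    histogram, GLCM, GLRLM, GLSZM, GLDZM, NGTDM, NGLDM families),
    stability-based feature selection via ICC(1,1) under segmentation
    perturbations, ensemble SVM and random-forest classification with ADASYN
    class rebalancing under nested cross-validation, and per-case
    percentile/sigma explanation reports against class-conditional training
    distributions. Includes a seeded synthetic fundus generator so the whole
    pipeline is exercisable without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    png,
    e1071,
    randomForest,
    caret,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
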