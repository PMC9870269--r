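Package: FRPSurv
Title: Fuzzy Recurrence Plot Pipeline for Two-Class Survival Prediction
    from Immunohistochemistry Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies immunohistochemistry (IHC) images into two
    survival classes by extracting flattened deep features from
    convolutional backbone architectures, compressing them with fuzzy
    c-means clustering, reconstructing a phase space by time-delay
    embedding, building fuzzy recurrence plots (FRPs) via max-min fuzzy
    relation composition, and classifying the FRPs as multi-feature time
    series with a bidirectional long short-term memory network. Includes
    a linear support vector machine baseline on deep or Haralick
    gray-level co-occurrence (GLCM) texture features, a stratified
    k-fold cross-validation harness with accuracy, sensitivity,
    specificity, precision and F1 reporting, and seeded generators for
    two-class stained-tissue-like images and class-structured feature
    vectors so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    e1071,
    EBImage,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, Clustering, FeatureExtraction
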