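Package: qkmorph
Title: Quantum and Classical Kernel Classification of Neuron Morphometries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible pipeline for multiclass neuron M-type
    classification from morphometric feature tables. Provides row
    filtering (missing values, zero soma surface, Mahalanobis outlier
    deletion), eleven feature rescaling transforms (standardization,
    range scalers, power transforms with maximum-likelihood lambda,
    quantile maps), Gini-impurity tree-based feature selection, adapters
    to classical feature extraction, a from-scratch statevector engine
    for diagonal Pauli-Z quantum feature maps with eight fidelity-kernel
    encodings (exact and shot-sampled), quantum kernel alignment trained
    by simultaneous perturbation stochastic approximation, the four
    classical support vector machine kernels, and a precomputed-kernel
    one-vs-one SVM with stratified cross-validation and a benchmark grid.
    A seeded synthetic morphometry generator emulates the statistical
    structure of L-Measure feature tables so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    kernlab,
    randomForest,
    rpart,
    xgboost,
    vegan,
    corpcor,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
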