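Package: idcoding
Title: Identity-Selectivity Screening, Decoding and Representational
    Geometry for Unit Populations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing how face identities are encoded by
    populations of responsive units, whether artificial network units or
    recorded neurons. Provides ANOVA-based identity-selectivity screening
    with a 2-SD encoded-identity criterion and single-identity (SI) /
    multiple-identity (MI) classification; cross-validated RBF-SVM
    population decoding by unit group; lesion and weight-shuffle
    perturbation of a layered convolutional fixture network; spike-train
    windowing, baseline normalization and reliability filtering;
    representational dissimilarity matrices with label-shuffle
    permutation tests and temporal sliding-window dynamics; and detection
    of region-based feature coding in low-dimensional stimulus embeddings
    via kernel density estimation with cluster-level permutation control.
    A synthetic-data module plants ground-truth selectivity, latency and
    face-space geometry so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    png,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, Classification, DimensionReduction, Visualization
RoxygenNote: 7.3.3
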