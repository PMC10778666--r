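Package: grapemet
Title: Untargeted Grape-Juice Metabolomics: Formula Assignment,
    Cross-Platform Feature Alignment and Chemometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Data-processing chain for untargeted mass-spectrometry
    metabolomics of grape juice: elemental-composition assignment of
    ultra-high-resolution mass peaks by bounded mass decomposition and
    mass-difference-network propagation, within- and cross-platform
    feature alignment with isobar accounting, feature-matrix filtering,
    imputation, batch correction and univariate screening, chemical-space
    description (van Krevelen coordinates, compound-class composition,
    coverage comparisons), and multivariate discrimination (PCA, two-class
    OPLS-DA with VIP scores and permutation validation, RDA variance
    partitioning).  A synthetic-data generator produces ground-truthed
    direct-infusion and LC-style peak lists so that every pipeline stage
    is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
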