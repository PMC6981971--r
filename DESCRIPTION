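Package: spectralGS
Title: Spectral Reflectance Indices for Indirect Selection and Genomic
    Prediction of Grain Yield
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for using canopy spectral reflectance indices (NDVI,
    NDRE, NWI-1, SR) from high-throughput phenotyping as secondary traits
    in winter-wheat breeding. Computes plot-level vegetation indices,
    adjusts augmented-design field trials (per-environment BLUEs and
    across-environment BLUPs with replicated checks), estimates REML
    variance components, broad-sense heritability, genetic correlations
    and Falconer indirect-selection statistics (response to selection,
    correlated response, relative selection efficiency), and fits
    ridge-regression BLUP genomic prediction models with optional
    secondary-trait fixed effects, including k-fold cross-validation and
    independent train/test validation. Also provides Roger's genetic
    distance, marker PCA, top-fraction selection-overlap comparisons,
    least-squares yield models, and a seeded synthetic-data generator
    emulating multi-environment augmented wheat trials so the full
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    lme4,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
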