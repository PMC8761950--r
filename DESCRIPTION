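Package: qgpanel
Title: Quantitative Genetics of Multi-Trait Diversity Panels in
    Randomized Complete Block Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for balanced randomized complete block
    (RCBD) diversity-panel trials with many quantitative traits, of the
    kind used in nutritional crop breeding. Provides per-trait RCBD
    analysis of variance with extraction of error, genotypic and
    phenotypic variance components; genetic parameters (genotypic and
    phenotypic coefficients of variation, broad-sense heritability with
    classification, genetic advance under truncation selection);
    genotypic and phenotypic correlation matrices estimated from
    variance and covariance components; path-coefficient decomposition
    of trait correlations into direct and indirect effects with
    collinearity diagnostics; multivariate structure of genotype means
    (correlation-matrix PCA, k-means clustering with silhouette
    validation); derived proximate-composition, colour-difference and
    radical-scavenging arithmetic; and a synthetic-trial generator with
    known genotypic covariance structure for validation, defaulting to
    a 64-genotype carrot panel with 3 blocks and 15 traits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
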