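Package: cismediatr
Title: Network-Directed Cis-Mediation Analysis of Trans-eQTL Associations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering trans-acting regulatory consequences of
    risk variants through cis-regulated mediator genes. The pipeline screens
    variant-transcript associations with covariate-adjusted linear models
    (expression principal components as latent-factor covariates), estimates
    a sparse undirected gene co-expression graph by Meinshausen-Buhlmann
    neighborhood selection with stability-based (StARS) regularization
    selection, forms candidate (variant L, cis-gene C, trans-gene T) trios
    from graph neighborhoods, and tests the causal chain L -> C -> T with a
    four-component intersection-union causal inference test, a
    mediated-proportion statistic M, and a genotype-stratified permutation
    robustness test. A synthetic-data generator with known causal and
    graphical ground truth supports end-to-end validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
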