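Package: phagephylo
Title: Phylogenetic Analysis of Bacteriophage Susceptibility Across Host Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how much of the variation in bacterial
    susceptibility to bacteriophage infection is explained by the host
    phylogeny. Converts raw plaque-assay, optical-density and qPCR records
    into analysis traits (including a probit hurdle decomposition of
    zero-inflated plaque titres), fits multivariate phylogenetic
    generalised linear mixed models by blocked Gibbs sampling with
    parameter-expanded covariance priors, derives repeatability,
    phylogenetic heritability and inter-trait correlations with highest
    posterior density intervals, reconstructs ancestral susceptibility
    states under Brownian motion, and evaluates phylogenetic
    leave-one-out prediction of held-out strains against a null model.
    Includes a synthetic-data generator with known ground truth for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    coda,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
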