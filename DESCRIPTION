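Package: deepfd
Title: Trait-Based Functional Diversity of Deep-Pelagic Fish Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trait-based analysis of deep-pelagic fish assemblages
    sampled along a depth gradient: trawl-biomass standardization and depth-layer
    assemblage tables; derivation of 26 foraging-related morphological traits from
    raw measurements with sparse-species exclusion and chained-equation (predictive
    mean matching) imputation; Gower dissimilarity on mixed trait types and a
    principal-coordinates functional space with quality assessment and convex-hull
    vertex identification; biomass-weighted functional richness, evenness,
    dispersion and divergence; trait-randomization null models with standardized
    effect sizes and a normality/skewness/percentile significance pathway;
    bootstrapped community-weighted trait means with a depth-layer PCA; functional
    rarity (uniqueness and depth-range restrictedness); and a synthetic-community
    generator with controllable assembly mechanisms (environmental filtering,
    limiting similarity) for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    cluster,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
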