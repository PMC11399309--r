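Package: traitclim
Title: Community-Weighted Trait Means and Trait-Climate Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for trait-based macroecology: community-weighted
    means (CWMs) of plant functional traits from vegetation-plot
    composition tables, bioclimatic variables (moisture index, mean
    temperature of the coldest month, mean growing-season temperature)
    from monthly climate grids, constrained and unconstrained ordination
    of trait covariation, generalized additive trait-climate surfaces
    with Shapley predictor importance and convex-hull extrapolation
    masking, gridded trait prediction from land-cover-derived fractional
    plant-group cover, and regression-based map agreement metrics. Ships
    a seeded synthetic-world generator with planted latent trait
    dimensions and climate signals so every stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    pracma,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
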