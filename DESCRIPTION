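Package: mossar
Title: Scale-Dependent Species-Area Relationships and Elevational
    Richness Gradients from Nested-Plot Surveys
Version: 0.1.0
Authors@R:
    person("mossar", "maintainers", email = "mossar@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing nested-plot community surveys along
    elevational gradients: per-plot power-law species-area relationship
    (SAR) fitting with standard-error weights, a discrete mid-domain-effect
    (MDE) Monte Carlo null model with an exact oracle, penalized-spline
    trend models with spatial-autocorrelation diagnostics (Moran's I),
    boosted regression trees with cross-validated meta-parameter tuning
    and permutation-based conditional variable importance, regressions of
    model performance and importance scores against spatial scale, and
    drop-one / noise-perturbation sensitivity checks.  A synthetic-data
    generator with known ground truth (planted c- and z-surfaces, species
    elevational ranges, coarse-raster covariates) makes every stage
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    mgcv,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
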