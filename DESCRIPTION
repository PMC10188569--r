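Package: entniche
Title: Maximum-Entropy Species Distribution Modelling on Gridded Climate Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Presence-background habitat-suitability modelling with an
    L1-regularized maximum-entropy (Gibbs) density over background cells.
    Reads and writes ESRI ASCII grid rasters, screens collinear bioclimatic
    predictors, expands predictors into linear, quadratic, product, threshold
    and hinge features, fits the penalized model by coordinate descent,
    tunes feature classes and regularization multipliers by cross-validation
    and AICc, evaluates models with rank AUC, the true skill statistic and
    the continuous Boyce index, and projects fitted models onto climate
    scenario stacks with five-class suitability classification and
    spherical-geometry area-change accounting. Includes a synthetic
    bioclimatic landscape generator with a known suitability surface for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
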