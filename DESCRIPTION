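Package: pharmaniche
Title: Habitat Suitability Modelling and Quality Zoning for Medicinal Plants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline linking the ecological niche of a
    medicinal plant to the spatial quality of the crude drug it yields.
    Reads species occurrences and aligned environmental raster layers
    (ESRI ASCII grids), fits a maximum-entropy species distribution model
    with percent-contribution, permutation-importance and jackknife
    diagnostics, iteratively selects main ecological factors by
    contribution and collinearity pruning, classifies suitability into
    zones (fixed breaks or Fisher-Jenks) with latitude-corrected areas and
    climate-scenario comparison, processes chromatographic fingerprints
    (peak detection, retention-time correction, common-peak matching,
    cosine similarity, PCA marker selection), links functional-factor
    concentrations to ecological covariates (Mann-Whitney tests, stepwise
    regression, Spearman correlation with factor clustering), and composes
    fuzzy-overlay quality-zoning maps. A synthetic-data module generates
    environmental stacks, occurrences, chromatograms and concentration
    tables with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
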