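Package: depdiff
Title: Deprivation Differentials and Self-Reported Morbidity in Small Areas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Small-area ecological regression of self-reported morbidity on
    area deprivation and the deprivation differential between an area and its
    contiguous neighbours. Builds queen-contiguity neighbour structures from
    lattices, GeoJSON polygons or edge lists; computes the spatial lag of a
    deprivation index (adjacent locality deprivation); orthogonalizes the two
    collinear deprivation measures by principal components into a target-area
    deprivation score and an uncorrelated deprivation-differential score; fits
    standardized bivariate and multivariate linear models of log10 morbidity
    percentages; and replicates the models within deprivation tertiles or
    geodemographic segments, reporting beta-ratio tables. Includes a seeded
    synthetic-data generator for lattice study regions with spatially
    autocorrelated deprivation and binomial morbidity counts, so the full
    pipeline is testable without external census or deprivation-index data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
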