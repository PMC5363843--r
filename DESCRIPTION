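Package: nightnets
Title: Representativeness of Partial-Night Mist-Net Sampling Schedules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for deciding whether partial-night mist-net schedules
    representatively sample a nocturnal bat assemblage. Builds
    schedule-restricted night-by-species capture matrices, computes a
    three-metric rarity index (local abundance, regional abundance,
    minimum-convex-polygon geographic range) with independence weights and
    quartile classes, locates per-species activity change points along the
    night-time gradient with Threshold Indicator Taxa Analysis (permutation
    z-scores, bootstrap purity and reliability, community z-sum thresholds),
    compares schedules by individual- and sample-based rarefaction with
    Chao-type extrapolation, and quantifies compositional congruence between
    a schedule and the full night by Procrustes rotation of principal
    coordinates (r = sqrt(1 - m^2), PROTEST significance) against a
    random-species-subset null model. Includes a synthetic capture-data
    generator with known activity and rarity structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
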