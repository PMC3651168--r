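Package: texbird
Title: Image Texture Analysis of Avian Density and Species Richness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Moving-window image texture (first-order variance and entropy,
    second-order co-occurrence contrast) at multiple grains and window
    extents, zonal summaries around sample points, foliage-height diversity
    and horizontal vegetation structure from field profiles, distance-sampling
    density estimation with AIC-selected detection functions, sample-based
    species-accumulation curves, and habitat regression with leave-one-out
    cross-validation, residual semivariograms and predictive mapping. Includes
    a synthetic landscape generator (habitat mosaic, reflectance rendering,
    constrained sample points, foliage profiles, point-count surveys) with
    known ground truth for recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
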