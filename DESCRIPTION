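Package: incisorarc
Title: Arc Geometry, Cross-Sectional Mechanics and Phylogenetic
    Regression for Ever-Growing Incisors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative biomechanics of diprotodont
    (ever-growing) incisors. Models the lower incisor as a circular arc
    fitted through three labial-surface landmarks and derives its radius
    of curvature, subtended angle, total/internal/external arc lengths
    and fraction of a circle; computes cross-sectional area and second
    moments of area from binary section rasters; and provides the
    comparative statistics used in this field: coefficient-of-variation
    summaries, pooled t and variance-ratio tests, a Fligner-Killeen
    scale test (with a mean-scaled variant addressing CV homogeneity),
    and phylogenetic generalized least squares under Brownian motion.
    Includes a synthetic-specimen generator (arcs, elliptical sections,
    pure-birth trees, Brownian traits) with known ground truth for
    end-to-end validation, and an end-to-end study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
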