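Package: hoiforest
Title: Pairwise and Higher-Order Neighbourhood Interactions in Mapped Forest Censuses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantifying pairwise and higher-order neighbour
    interactions from two-census mapped forest plot data. Computes
    size-weighted, distance-discounted neighbourhood crowding indices
    (conspecific and heterospecific, pairwise and higher-order), fits
    nested demographic growth and survival models per species, classifies
    model support by AIC, relates interaction coefficients and species
    richness to absolute latitude with exponential regressions, and
    summarises the cumulative multiplicative effect of neighbourhood
    interactions on demographic rates as a function of species abundance
    and latitude. Includes a synthetic multi-plot forest generator with
    known interaction coefficients for power analysis and parameter
    recovery studies, plus a configurable end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
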