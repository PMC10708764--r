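Package: forestagb
Title: Forest Above-Ground Biomass Inversion from Optical and SAR Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating forest above-ground biomass (AGB) from
    co-registered multispectral and synthetic-aperture-radar feature stacks.
    Computes per-tree AGB with a power-law allometric model and aggregates it
    to plot level, extracts an 86-variable candidate-predictor catalogue
    (optical bands, seven vegetation indices, grey-level co-occurrence
    texture measures, VV/VH backscatter, terrain and canopy variables),
    screens predictors by Pearson correlation, and fits three competing
    inversion models: stepwise linear regression, a single-hidden-layer
    neural network trained by Levenberg-Marquardt, and the same network with
    weights optimised by particle swarm optimisation.  Fitted models are
    evaluated on held-out plots (relative-error and R-squared summaries) and
    applied pixelwise to raster stacks to map biomass.  A seeded synthetic
    plot-inventory and raster generator with a known biomass-feature link
    makes every stage testable without confidential inventory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
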