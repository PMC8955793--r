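Package: qekc
Title: Quality-by-Design Optimization of Chiral Electrokinetic
    Chromatography Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for design-of-experiments based optimization of chiral
    capillary electrokinetic chromatography (cEKC) separations. Generates
    D-optimal run subsets of a three-level factorial candidate grid by
    Fedorov exchange, fits full-quadratic response-surface models on coded
    factors by ordinary least squares with significance-based backward
    elimination, and derives effect diagnostics (adjusted responses, Pareto
    charts of standardized effects, interaction profiles, contour maps with
    baseline-resolution iso-lines). Includes electropherogram peak
    detection with full-width-at-half-maximum resolution measurement,
    enantiomeric-ratio and calibration/LOD/LOQ/recovery computations, and a
    seeded synthetic-trace generator for end-to-end pipeline validation.
    Ships the amlodipine/maltodextrin enantioseparation study tables as
    worked fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
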