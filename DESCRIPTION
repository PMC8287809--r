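Package: mtflex
Title: Microtubule Flexural Rigidity from Thermal Shape Fluctuations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures the flexural rigidity of microtubules (and other
    semiflexible filaments) from thermally fluctuating shapes of
    cantilevered filaments. Provides a clamped-free beam eigenmode basis,
    a simulator that generates shape ensembles with defined rigidity and
    digitizes coordinates at a specified localization precision, a
    mode-variance rigidity estimator based on the equipartition theorem
    (arc-length geometry, midpoint-quadrature mode decomposition, and an
    origin-constrained slope fit), a simulation study quantifying how
    localization precision, filament length, and true rigidity bias the
    estimate, and the nonparametric Steel-Dwass all-pairs comparison with
    phase segmentation used to analyse growth-rate regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
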