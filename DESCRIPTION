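Package: rsmnet
Title: Response-Surface and Neural-Network Modelling of Bioprocess
    Optimisation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for second-order response-surface analysis of central
    composite designs (CCD) and for benchmarking the fitted polynomial
    against a single-hidden-layer tanh neural network. Builds CCDs in
    coded units, fits linear, two-factor-interaction and quadratic models
    by ordinary least squares, and produces the complete adequacy report:
    Type-III analysis of variance with lack-of-fit against pure error
    from replicated centre points, the R-squared family, PRESS and
    predicted R-squared, adequate precision, studentized-residual
    diagnostics and the Box-Cox transformation profile. Includes
    Derringer-Suich desirability optimisation over the design region,
    response-surface grids, per-model goodness-of-fit comparison (RASE,
    AAE/MAD, SSE), simulation of CCD responses from a known quadratic
    surface, and sigmoidal dose-response (IC50) fitting with tumour
    volume and growth-inhibition summaries for downstream bioassays.
    Ships the 30-run gold-nanoparticle biosynthesis optimisation dataset
    used throughout the documentation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    optparse
Config/testthat/edition: 3
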