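Package: fovs
Title: Absolute Abundance Estimation with Exotic Markers by Linear and
    Field-of-View Subsampling Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates absolute abundances (concentrations) of specimens
    from exotic-marker spiked samples, such as Lycopodium-spiked
    palynological preparations. Implements the classical sequential
    ('linear') count estimator and the two-stage field-of-view
    subsampling (FOVS) estimator with Poisson-based error propagation,
    effort models, and the closed-form sampling-design calculus that
    follows from them: error-versus-effort curves, optimal allocation of
    calibration and extrapolation fields of view, a method-determination
    test based on the critical specimen density, and effort requirements
    for a target precision. A Monte Carlo simulator of virtual study
    areas validates accuracy and precision of both estimators under
    known conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
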