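Package: mbwsim
Title: Multi-Scale Simulation of the Multiple-Breath Washout Test
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the nitrogen multiple-breath washout (MBW) lung
    function test with a multi-scale model of the human lung: an
    asymmetric fractal tree of conducting airways coupled to trumpet-shaped
    acinar compartments (trumpet lobules), a nonlinear lumped-parameter
    ventilation model driven by a prescribed tracheal flow, and
    one-dimensional inert-gas advection-diffusion transport with Taylor
    dispersion on the whole network. Lobular perturbations of compliance,
    residual volume and flow resistance can be applied in regional or
    local spatial patterns to study ventilation inhomogeneity. Washout
    analysis includes breath segmentation, bi-exponential decay fits of
    the end-expiratory concentration envelope, normalized phase III
    slopes and the lung clearance index (LCI).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
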