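Package: mtcontract
Title: Active-Fluid Modeling of Microtubule Network Contraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the bulk contraction of stabilized microtubule
    networks in confined channels as an active fluid. Simulates the
    one-dimensional free-boundary continuum equations in which a
    density-saturating motor-generated active stress drives contraction
    against viscosity and wall drag, derives the scaling of the contraction
    timescale with channel width, and provides the estimation procedures used
    on contraction data: exponential-relaxation fits of the fraction
    contracted, least-squares matching of simulated density profiles,
    sigmoid dose-response (EC50) fits for motor inhibition, and final network
    density estimation from fluorescence. An image-analysis chain extracts
    widths, length-averaged density profiles, and particle image velocimetry
    fields from fluorescence stacks, and seeded synthetic-microscopy
    generators produce movies and datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    tiff,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
Config/testthat/edition: 3
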