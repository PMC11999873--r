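Package: sleflow
Title: Conformal Invariance and Schramm-Loewner Evolution Analysis of
    Two-Dimensional Flow Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical analysis of zero-vorticity isolines in gridded
    two-dimensional velocity fields, such as those obtained by particle
    image velocimetry of collectively moving cell monolayers.  Computes
    vorticity with a fourth-order five-point stencil, traces oriented
    zero-vorticity contours with an orientation-preserving marching
    squares algorithm, and tests the resulting curve ensembles for scale
    and conformal invariance: perimeter/gyration-radius fractal
    dimensions of complete and accessible cluster perimeters,
    winding-angle variance scaling, Schramm left-passage probability
    fits, and Loewner driving-function extraction by the vertical slit
    map ("zipper").  Ships exact synthetic references with known ground
    truth: chordal interfaces of critical site percolation on the
    triangular lattice (the SLE(6) class), forward SLE(kappa) traces
    generated from Brownian driving, and a scaled-down active nematic
    hydrodynamics simulator (Q-tensor finite differences coupled to a
    lattice Boltzmann flow solver).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
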