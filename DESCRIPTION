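Package: permstrut
Title: Diffusivity Measurement and Oxygen-Limited Growth Simulation for
    Permeable-Strut Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of fluorescence recovery after photobleaching (FRAP)
    traces from nanofibrous line patterns and hydrogel films: half-time
    extraction, uniform-disk diffusion coefficients, and obstruction-model
    rescaling of a measured macromolecule diffusivity ratio to an oxygen
    diffusivity estimate.  Companion three-dimensional reaction-diffusion
    model of spatially patterned tissue-engineering scaffolds: voxelized
    lattice and staggered strut arrangements, heterogeneous oxygen diffusion
    with Michaelis-Menten consumption, Monod cell proliferation, and the
    derived saturated-depth and saturation-time metrics, including sweeps
    over strut permeability and volume fraction.  A synthetic FRAP generator
    (spectral and explicit two-dimensional diffusion solvers) provides
    oracle-checked test data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
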