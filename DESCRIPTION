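Package: latticeshed
Title: Boundary-Driven Lattice Tumor Growth and Spatially Biased ctDNA Shedding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of solid tumor evolution on a 2D lattice with
    boundary-driven (Eden) growth, driver mutation accumulation under an
    infinite-sites model, and spatially heterogeneous apoptosis between a core
    sanctuary site and the tumor edge. Couples the simulated clone structure to
    a calibrated model of circulating tumor DNA (ctDNA) fragment shedding and
    variant allele frequency (VAF) sampling in a blood draw, and computes
    blood-versus-tissue distortion metrics: clone fraction differences, inverse
    Simpson clonal diversity, detectable driver counts under sequencing
    detection limits, and the analytic two-compartment bound on the maximum
    clone fraction difference.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
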