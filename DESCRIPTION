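Package: dynloop
Title: Dynamic Loop Polymer Simulations of Interphase Chromatin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Lattice Monte Carlo simulator and analysis toolkit for the
    Dynamic Loop model of interphase chromatin folding. Implements the
    three-dimensional bond fluctuation method for a self-avoiding polymer
    with transient loop bonds whose formation probability depends on contour
    separation (short-range versus long-range looping) or on a layout of
    topological domains, with Poisson-distributed bond lifetimes. Provides
    the full simulation protocol (self-avoiding-walk initialisation,
    two-phase equilibration, production sampling with radius-of-gyration
    autocorrelation control), ensemble observables (mean square distance
    versus contour separation, plateau compaction, looping-parameter heat
    maps, loop counts), and FISH-style locus-geometry analyses (mean square
    distance versus genomic distance, normalised radial nuclear position)
    together with a synthetic probe-pair table generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
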