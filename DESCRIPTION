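Package: nebar
Title: Bidirectional Nonequilibrium Free-Energy Estimation for Alchemical
    Binding Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for dual-topology nonequilibrium alchemical
    relative binding free energy (RBFE) calculations.  Reads plain-text
    nonequilibrium work samples from bound and unbound alchemical legs,
    computes bidirectional (Bennett acceptance ratio, with and without
    work-distribution convolution) and unidirectional (Jarzynski,
    second-cumulant Gaussian) free-energy estimates with bootstrap
    uncertainties and a posteriori finite-size corrections, validates
    RBFE networks through cycle-closure conditions and shortest-path
    indirect estimates, and provides synthetic work generators
    (Crooks-consistent Gaussian and bimodal samplers, driven Langevin
    toys) with known ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
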