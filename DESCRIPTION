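Package: pmfish
Title: Self-Propelled Particle Schools and Boltzmann Inversion of Fish
    Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates schooling fish as self-propelled particles in a
    circular arena (zonal repulsion, Vicsek-type alignment, order-dependent
    speed, Gaussian heading noise, wall avoidance) and infers effective
    pairwise interactions from positional data by direct Boltzmann
    inversion: pair distribution function with an edge correction for the
    bounded arena, potential of mean force, and mean interaction force,
    together with group geometry (convex-hull area, density, packing
    fraction), polar-order statistics, angular occupancy maps, and
    Metropolis-sampled validation ensembles with known pair potentials.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
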