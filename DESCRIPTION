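Package: lumensim
Title: Center-Based Simulation of Lumen Morphogenesis in Viscous Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A seeded, configurable three-dimensional multi-agent (center-based)
    simulator of lumen morphogenesis. Spherical cells grow exponentially with a
    mechanoregulated, pressure-sensitive cycle, divide with oriented cleavage,
    polarize around a midbody, and secrete fluid particles into the nascent
    lumen under a hydrostatic-pressure gate. Agents interact through short-range
    adhesive-repulsive pairwise potentials and move by overdamped dynamics with
    Stokes drag against a viscous extracellular matrix. Includes lumen
    identification and volumetry (morphological ball-closing of the fluid body),
    replicate sweeps across matrix viscosities, trajectory/event/snapshot
    export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
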