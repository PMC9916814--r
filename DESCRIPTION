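Package: dendromicelle
Title: Lattice Self-Consistent Field Modelling of Dendron-Tail Surfactant Micelles
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Numerical Scheutjens-Fleer self-consistent field (SF-SCF)
    machinery for the self-assembly of hybrid amphiphiles made of a charged
    polylysine dendron head and one or more linear hydrophobic tails.
    Provides a united-atom molecule builder for asymmetric lysine dendrons,
    curved one-dimensional lattices (planar, cylindrical, spherical) with a
    discrete Poisson solver, tree-chain propagators, a damped/Anderson
    fixed-point SCF solver, small-system micelle thermodynamics (grand
    potential, chemical potential, aggregation number, critical micelle
    concentration, morphology transitions), and structural and electrostatic
    observables (core radius, corona thickness, cumulative charge, effective
    radius and charge, zeta potential, corona stratification diagnostics).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
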