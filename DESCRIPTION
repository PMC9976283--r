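Package: permeonics
Title: Ion Permeation, Solvation and Charge-Transfer Analysis for Channel Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics and QM/MM studies of divalent
    cation permeation through ion channels. Detects permeation events and converts
    them to single-channel currents and conductances, builds axial and axial-radial
    ion occupancy maps with Boltzmann inversion to free-energy profiles, computes
    radial distribution functions, running coordination numbers and hydration
    statistics along the pore axis, and quantifies electronic polarization: electron
    density differences on volumetric grids, Voronoi-partitioned per-atom charge
    transfer, and localized-orbital (Wannier-style) center classification, shifts and
    molecular dipoles. Includes synthetic generators (Brownian pore trajectories,
    analytic Gaussian densities, hydrated-ion cluster geometries) so every stage is
    testable without external data, and a compact Gaussian-basis Hartree-Fock engine
    used to produce quantum-mechanical reference densities and localized orbital
    centers for hydrated-ion clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
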