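Package: vegfr2sim
Title: Reaction-Diffusion Simulation of VEGFR2 Relocation on a Spreading
    Endothelial Cell Membrane
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the relocation of VEGFR2 receptors on the membrane of an
    endothelial cell adhering to a ligand-coated slide. The membrane is treated
    as an axisymmetric surface advecting through a prescribed, volume-conserving
    family of spherical-cap shapes; receptor transport is a surface
    reaction-diffusion problem in referential (pulled-back) concentrations with
    an instantaneous receptor-ligand equilibrium closure, gap-dependent ligand
    availability, and an optional mobile/immobile receptor split calibrated
    from FRAP. Also provides the two short-range electrostatic binding-traction
    models used to assess whether electrostatics can drive cell spreading,
    contact complementarity checks, and writers for time series and mesh
    snapshots.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
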