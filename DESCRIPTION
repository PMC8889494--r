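Package: periodicrism
Title: Periodic 3D-RISM Integral-Equation Solvent Model for Molecular Crystals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Solves the three-dimensional reference interaction site model
    (3D-RISM) integral equations for a solute in a fully periodic unit cell,
    as needed for molecular crystals where the solvent occupies the channels
    between close-packed solute images.  The bulk solvent susceptibility is
    computed by a built-in radial (1D) RISM stage for rigid multi-site
    solvents with dissolved salt; the periodic solute potential is
    synthesized by smooth particle-mesh Ewald electrostatics plus
    minimum-image Lennard-Jones; the Ornstein-Zernike convolution is closed
    with the HNC or PSE-n (including Kovalenko-Hirata) closures and
    accelerated by MDIIS.  Net-charged solutes are handled by a
    background-charge renormalization of the direct correlation function so
    that the converged solvent distribution neutralizes the unit cell, with
    the matching correction term in the closed-form excess chemical
    potential, analytic solvation forces, and a Wigner finite-size
    correction for dilute-limit studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, Matrix, pracma, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
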