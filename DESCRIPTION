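Package: fibrilmech
Title: Mechanical Properties of Amyloid Fibrils from Thermal Fluctuation Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quasi-harmonic (principal component) analysis of C-alpha fluctuation
    trajectories of amyloid fibrils, classification of the principal modes against
    continuum Euler-Bernoulli beam mode shapes, and inversion of the beam frequency
    relations into bending rigidity, persistence length, torsional and axial
    stiffness. Also provides the accompanying conformational metrics (RMSD,
    RMSF, inter-layer dihedral twist, bending angle, twist-disorder order
    parameter, backbone hydrogen-bond density, Shrake-Rupley solvent-accessible
    surface area and the SASA-proportional nonpolar solvation energy), a builder
    for idealized cross-beta steric-zipper fibril polymorphs, and a synthetic
    generator of thermally fluctuating elastic-beam trajectories with known
    ground-truth mechanics for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
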