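Package: starkfield
Title: Electric Fields Along Vibrational Stark Probes in Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the electric field a protein exerts along a carbonyl
    vibrational Stark probe bond. Provides point-charge (Coulomb)
    electrostatic potentials and bond-projected fields with probe-ring
    exclusions, per-residue and solvent field decomposition, trajectory
    averaging and hydrogen-bond occupancy analysis; fragment-based
    quantum-style potentials assembled by the electrostatically embedded
    generalized molecular fractionation with conjugate caps (EE-GMFCC)
    scheme with hydrogen link atoms, generalized concap two-body
    corrections and a pluggable ESP backend; and the Stark/Eyring
    analytics that relate field magnitude to vibrational frequency shifts
    and activation free energies. Includes synthetic structure, ligand and
    trajectory generators with analytic field benchmarks so the whole
    pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
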