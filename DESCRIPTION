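Package: slowtight
Title: Slow Tight-Binding Inhibition Kinetics and Protease-Inhibitor
    Interface Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of slow, tight-binding inhibition of serine
    proteases by Kunitz-type inhibitors, and of the structural interface
    of protease-inhibitor complexes.  Provides deterministic simulation
    of progress curves under one-step, two-step and irreversible binding
    schemes with competitive substrate turnover; a seeded generator of
    noisy synthetic progress-curve families; simultaneous (global)
    nonlinear regression of curve families; model discrimination by
    small-sample Akaike weights and the variance-ratio (F) test; derived
    inhibition constants (Ki, association/dissociation half-lives) with
    propagated uncertainty; and a structural geometry suite covering
    least-squares superposition, docking angles, chi1 dihedrals,
    contact classification, Lee-Richards solvent-accessible surface
    area and buried interface area on PDB coordinate files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    bio3d,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
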