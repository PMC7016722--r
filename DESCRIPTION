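Package: efdyn
Title: EF-Hand Calcium-Binding Dynamics from Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trajectory analysis for EF-hand calcium-binding proteins such as
    the S100A1 homodimer. Reads multi-model PDB and GRO structures and
    trajectories, provides an atom-selection language, Kabsch superposition,
    RMSD/RMSF, the three-point interhelical (helix-loop-helix opening) angle
    with windowed statistics, Shrake-Rupley solvent-accessible surface area,
    inter-subunit contact maps with distance classes, geometric hydrogen-bond
    counting, calcium-ion encounter and total-residence-time statistics,
    binding-site occupancy, hydration-shell water counting, and GROMOS-style
    conformational clustering with temporal cluster distributions. A synthetic
    toy-dimer trajectory generator with exact scripted ground truth makes
    every analysis stage verifiable without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
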