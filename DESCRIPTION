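Package: confens
Title: Conformational Ensemble Analysis for Protein Fragments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing conformational ensembles of protein
    fragments from multi-model PDB files or synthetic trajectories:
    rigid-body (Kabsch) superposition and pairwise RMSD matrices,
    per-frame RMSD time series and per-residue RMSF profiles, backbone
    phi/psi dihedral computation with circular statistics and angular
    state classification, and fixed-radius RMSD k-means ("kclust"
    style) clustering of fragment conformations within and across
    trajectories, with occupancy and overlap reporting. Includes a
    synthetic-ensemble generator with known ground truth (Markov state
    switching, Gaussian coordinate noise, arbitrary rigid-body motion)
    so every analysis stage is testable without molecular-dynamics
    trajectories. Motivated by the study of DNA-driven conformational
    selection in the glucocorticoid receptor DNA-binding-domain lever
    arm.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
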