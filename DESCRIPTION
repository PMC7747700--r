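Package: allonet
Title: Ensemble Interaction Persistence, Dynamical-Network Allostery, and
    Binding/Stability Assay Models for Nuclear-Receptor Ligand Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis layer for comparing stereoisomeric nuclear-receptor
    agonists. Reads multi-model PDB ensembles and plain-text trajectories,
    measures per-model hydrogen-bond, edge-to-face pi-pi stacking and
    water-network criteria and their persistence over an ensemble, computes
    Kabsch superpositions, RMSD/RMSF profiles, C-alpha correlation matrices
    and ligand/protein B-factor ratio statistics, builds contact-filtered
    correlation-weighted dynamical networks with optimal and suboptimal
    path enumeration between source and sink residues, and fits
    competition fluorescence-polarization binding curves (probe-corrected
    Ki) and Boltzmann thermal melts (Tm, delta-Tm). Includes synthetic-data
    generators with exactly planted interaction occupancies, planted
    correlation corridors, and noisy assay curves for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
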