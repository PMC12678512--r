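Package: sapflex
Title: Conformational Analysis of Saposin-Fold Hinge Proteins from
    Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for open/closed conformational dynamics of
    saposin-fold proteins such as pulmonary surfactant protein B (SP-B)
    from molecular dynamics trajectories stored as multi-model PDB files
    or plain coordinate tables. Provides Kabsch superposition with RMSD
    and mass-weighted per-residue RMSF profiles, diagnostic inter-helix
    residue separations with open/closed/partially-open classification,
    Boltzmann-inversion two-distance free-energy landscapes with minimum
    detection, k-means clustering of superposed frames, Kabsch-Sander
    (DSSP) secondary-structure assignment with helicity occupancy maps,
    radial solvent distribution functions about protein regions, and a
    synthetic two-flap hinge-protein trajectory generator with two-state
    Markov switching that supplies ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
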