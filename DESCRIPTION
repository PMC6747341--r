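Package: iondyn
Title: Domain Motion, Ion Coordination and Interaction-Entropy Analysis of
    Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-simulation analysis toolkit for metalloprotein molecular
    dynamics trajectories, built around the workflow used to characterise
    matrix metalloproteinase-2 and its associated Zn2+ and Ca2+ ions:
    superposition-based conformational statistics (RMSD, RMSF, radius of
    gyration, inter-domain centre-of-mass distances, periodic minimum image
    distance, Schlitter configurational entropy), dihedral principal component
    analysis with free-energy landscapes and k-means conformational families,
    dynamic cross-correlation and Cartesian PCA of domain motions, ion
    hydration analysis (radial distribution functions, shell occupancies,
    coordination numbers, Shrake-Rupley solvent accessible surface area),
    molecular-mechanics interaction energies with interaction-entropy
    estimates, bootstrap errors, Tukey-fence identification of significantly
    interacting residues, and coordination-geometry classification. A
    synthetic-trajectory module generates systems with planted ground truth
    so every stage is testable without a production simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    cluster,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
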