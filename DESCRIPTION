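Package: gpcrtraj
Title: Rotamer Switches, Hydration, and Helix Geometry in GPCR Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise the activation behaviour of G
    protein-coupled receptors (GPCRs) from molecular-dynamics
    trajectories. Reads multi-model PDB trajectories, assigns
    Ballesteros-Weinstein generic residue numbers from per-helix anchors,
    computes side-chain dihedral (chi) time series and detects rotamer
    toggle-switch events, counts water molecules in hydration shells
    around conserved residues and motifs, tracks helix kink angles about
    a proline pivot, computes superposition RMSD of transmembrane
    regions, measures distances between intracellular helix ends, and
    clusters frames into inactive/intermediate/active conformational
    states. Ships a synthetic 7-helix-bundle trajectory generator with
    planted ground truth so every analysis stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
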