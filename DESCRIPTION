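Package: flavoreact
Title: Reactivity and Trajectory Analysis of Flavoenzyme-Nitroaromatic Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking why a flavoenzyme such as xenobiotic reductase B
    processes some nitroaromatic substrates and not others. Computes conceptual-DFT
    global reactivity descriptors (electronegativity, hardness, electrophilicity,
    electrodonating/electroaccepting powers) from frontier orbital energies;
    analyzes hydride acceptor-donor distance series and distributions over
    enzyme-ligand trajectories; clusters ligand poses with DBSCAN on pairwise
    RMSD matrices and reports medoid representatives and contact residues;
    builds promolecular-density non-covalent-interaction (NCI) grids with the
    reduced density gradient and sign(lambda2)*rho classification; and provides
    point-charge electrostatic potential maps and ring-current-strength
    aromaticity bookkeeping. A synthetic-data module generates enzyme-ligand
    trajectories with planted pose modes so every stage is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
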