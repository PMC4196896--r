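Package: microswitchr
Title: Micro-Switch Conformational Analysis of GPCR Molecular Dynamics
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy analysis of G protein-coupled receptor (GPCR)
    micro-switch dynamics from molecular dynamics trajectories:
    Ballesteros-Weinstein generic residue numbering, per-frame distance
    series with threshold classification and engagement statistics for
    the P-I-F motif, D(E)/RY salt bridge and ionic lock, helix-axis
    rotation measurement from C-alpha coordinates, water-occupancy grids
    and ligand contact frequencies, and reconstruction of
    two-dimensional free-energy surfaces from well-tempered
    multiple-walker metadynamics hills logs.  A synthetic-trajectory
    generator (two-state Markov switching, rigid rotating helices,
    solvated boxes, and an overdamped Langevin walker with on-the-fly
    hill deposition) provides ground-truth inputs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
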