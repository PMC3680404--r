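Package: transportcv
Title: Collective-Variable Analysis of Alternating-Access Transporter Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying ligand-induced conformational states of
    neurotransmitter-sodium-symporter (NSS) fold transporters from multi-model
    PDB trajectories. Implements Shrake-Rupley solvent-accessible surface area
    over configured residue sets, SVD-based Kabsch superposition with RMSD and
    RMSF, gating-network minimum distances, scaffold-bundle centre-of-mass
    collective variables for the extracellular and intracellular faces, TM1a
    kink angles, ion displacement along the membrane normal, ligand contact
    occupancy, and a two-dimensional conformational-state classification
    against reference structures. Ships a synthetic toy-transporter generator
    with ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
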