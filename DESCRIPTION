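Package: pfrkit
Title: Structural Analysis of Peptide-Flanking Residues in MHC Class II Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for dissecting how peptide-flanking residues (PFRs) of
    HLA class II epitopes behave inside and outside the binding groove.
    Reads PDB/mmCIF coordinate files into tidy atom tables, assigns the
    P1-P9 core register and partitions a bound peptide into N-terminal
    PFRs, core and C-terminal PFRs, enumerates peptide-to-receptor atomic
    contacts split into van der Waals contacts and distance-criterion
    hydrogen bonds, profiles per-residue crystallographic B-factors,
    classifies four-residue windows against ideal beta-turn dihedral
    geometry (type II beta-hairpin, glycine-extended), detects
    serine/threonine-capped (ST) loops, and superposes matched loop
    segments for RMSD. Multi-model coordinate ensembles are analysed as
    trajectories: mass-weighted rigid-body fitting, per-residue Calpha
    RMSF, per-residue contact fractions, dihedral-window occupancy time
    series, and hierarchical agglomerative conformational clustering.
    Includes synthetic-data builders (ideal-dihedral peptide construction,
    planted contact scenes, jitter and two-state switching trajectories)
    that carry exact ground-truth ledgers for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
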