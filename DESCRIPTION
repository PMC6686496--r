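Package: dfirescore
Title: Knowledge-Based Protein-Ligand Scoring with a Distance-Scaled
    Ideal-Gas Reference State
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives a distance-dependent statistical potential for
    protein-ligand interactions from protein monomer structures using the
    distance-scaled, finite, ideal-gas reference (DFIRE) state. Protein
    atoms carry 167 residue-specific heavy-atom types; pair counts are
    collapsed onto 11 SYBYL mol2 ligand atom types so that complexes can
    be scored without protein-ligand training structures. Includes
    readers for PDB receptors and multi-pose mol2 ligand files, pose
    rescoring, and the standard assessment protocols for scoring,
    docking, ranking and virtual-screening power (Pearson correlation
    and regression error, RMSD-based pose success rates, per-cluster
    ranking, enrichment factors, ROC AUC and logAUC), together with a
    seeded synthetic-data generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
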