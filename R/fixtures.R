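# Synthetic structures for testing and calibration.
#
# These generators optimise for atom-type coverage and statistical
# control, not stereochemical realism: geometry is a Calpha random walk
# with jittered side chains and box-uniform ligands. They exercise every
# pipeline stage end to end; do not train production potentials on them.

.unit_sphere <- function(n) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

#' Generate a synthetic protein chain
#'
#' Residues are drawn uniformly from the 20 standard amino acids with
#' the correct heavy-atom complement for each; Calpha atoms follow a
#' 3.8 Angstrom random walk and the remaining heavy atoms are placed at
#' random offsets within 2.5 Angstrom of their Calpha. Every emitted
#' atom is typeable by construction. Output is byte-reproducible per
#' seed.
#'
#' @param n_residues Number of residues (0 gives an empty structure).
#' @param seed Integer seed.
#' @param path Optional path; if given the chain is also written as a
#'   PDB file (via [write_pdb_atoms()]).
#' @param chain_id Chain identifier.
#' @return Atom tibble in [read_pdb_chain()] layout.
#' @export
simulate_protein <- function(n_residues, seed = 1L, path = NULL,
                             chain_id = "A") {
  atoms <- withr::with_seed(seed, {
    if (n_residues == 0L) {
      tibble(residue_name = character(), atom_name = character(),
             residue_seq = character(), chain_id = character(),
             x = double(), y = double(), z = double(),
             occupancy = double(), element = character())
    } else {
      res <- sample(names(.residue_atoms), n_residues, replace = TRUE)
      ca <- apply(rbind(c(0, 0, 0), 3.8 * .unit_sphere(n_residues - 1L)),
                  2, cumsum)
      ca <- matrix(ca, ncol = 3)
      purrr::map_dfr(seq_len(n_residues), function(i) {
        nm <- .residue_atoms[[res[i]]]
        off <- runif(length(nm), 0.8, 2.5) * .unit_sphere(length(nm))
        off[nm == "CA", ] <- 0
        tibble(residue_name = res[i], atom_name = nm,
               residue_seq = as.character(i), chain_id = chain_id,
               x = round(ca[i, 1] + off[, 1], 3),
               y = round(ca[i, 2] + off[, 2], 3),
               z = round(ca[i, 3] + off[, 3], 3),
               occupancy = 1, element = substr(nm, 1, 1))
      })
    }
  })
  if (!is.null(path)) write_pdb_atoms(atoms, path)
  atoms
}

#' Write an atom tibble as a PDB file
#'
#' Thin wrapper over [bio3d::write.pdb()] for fixture output;
#' deterministic formatting so fixed seeds give byte-identical files.
#'
#' @param atoms Atom tibble ([read_pdb_chain()] layout).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_atoms <- function(atoms, path) {
  if (nrow(atoms) == 0L) {
    writeLines("END", path)
    return(invisible(path))
  }
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(cbind(atoms$x, atoms$y, atoms$z))),
                   type = rep("ATOM", nrow(atoms)),
                   resno = as.integer(atoms$residue_seq),
                   resid = atoms$residue_name,
                   eleno = seq_len(nrow(atoms)),
                   elety = atoms$atom_name,
                   chain = atoms$chain_id,
                   o = atoms$occupancy, b = rep(0, nrow(atoms)),
                   elesy = atoms$element)
  invisible(path)
}

#' Generate a synthetic ligand pose
#'
#' Heavy atoms drawn uniformly from the 11 canonical SYBYL types with
#' coordinates uniform in a cube of the given edge length.
#'
#' @param n_atoms Number of atoms (>= 1).
#' @param seed Integer seed.
#' @param box Cube edge length in Angstrom.
#' @param center Length-3 numeric center of the cube.
#' @param path Optional path; if given, written as a mol2 file.
#' @param name Molecule name.
#' @return Single-pose tibble in [read_mol2_poses()] layout.
#' @export
simulate_ligand <- function(n_atoms, seed = 1L, box = 15, center = c(0, 0, 0),
                            path = NULL, name = "LIG") {
  stopifnot(n_atoms >= 1L)
  pose <- withr::with_seed(seed, {
    ty <- sample(.canonical_mol2, n_atoms, replace = TRUE)
    tibble(
      pose_id = paste0(name, "_1"), molecule_name = name,
      atom_name = paste0(sub("\\..*", "", ty), seq_len(n_atoms)),
      sybyl = ty,
      x = round(runif(n_atoms, -box / 2, box / 2) + center[1], 4),
      y = round(runif(n_atoms, -box / 2, box / 2) + center[2], 4),
      z = round(runif(n_atoms, -box / 2, box / 2) + center[3], 4),
      status = "typed",
      type_index = match(ty, .canonical_mol2)
    )
  })
  if (!is.null(path)) write_mol2_poses(pose, path)
  pose
}

#' Write poses as a (multi-molecule) SYBYL mol2 file
#'
#' One `@<TRIPOS>MOLECULE` block per pose, in input order, no bonds
#' (pair potentials are connectivity-free). Readable by
#' [read_mol2_poses()] and by [bio3d::read.mol2()].
#'
#' @param poses Pose tibble (one or many poses).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mol2_poses <- function(poses, path) {
  blocks <- purrr::map_chr(split_poses(poses), function(p) {
    paste(c("@<TRIPOS>MOLECULE",
            p$molecule_name[1],
            sprintf("%5d %5d %5d %5d %5d", nrow(p), 0L, 0L, 0L, 0L),
            "SMALL",
            "NO_CHARGES",
            "",
            "@<TRIPOS>ATOM",
            sprintf("%7d %-8s %9.4f %9.4f %9.4f %-9s %3d %-8s %9.4f",
                    seq_len(nrow(p)), p$atom_name, p$x, p$y, p$z,
                    p$sybyl, 1L, p$molecule_name[1], 0)),
          collapse = "\n")
  })
  writeLines(paste(blocks, collapse = "\n"), path)
  invisible(path)
}

#' Rigidly and/or randomly perturb a pose
#'
#' Adds an optional rigid translation plus i.i.d. Gaussian coordinate
#' noise — a cheap stand-in for alternative docking poses at controlled
#' RMSD from a native pose.
#'
#' @param pose Single-pose tibble.
#' @param shift Length-3 rigid translation (Angstrom).
#' @param noise_sd Per-coordinate Gaussian noise SD (Angstrom).
#' @param seed Integer seed.
#' @param pose_id New pose id.
#' @return The perturbed pose tibble.
#' @export
perturb_pose <- function(pose, shift = c(0, 0, 0), noise_sd = 0,
                         seed = 1L, pose_id = NULL) {
  withr::with_seed(seed, {
    n <- nrow(pose)
    pose$x <- pose$x + shift[1] + rnorm(n, 0, noise_sd)
    pose$y <- pose$y + shift[2] + rnorm(n, 0, noise_sd)
    pose$z <- pose$z + shift[3] + rnorm(n, 0, noise_sd)
  })
  if (!is.null(pose_id)) pose$pose_id <- pose_id
  pose
}

#' Sample shell counts implied by a known potential
#'
#' Inverts the potential definition for one (protein type, mol2 type)
#' pair: bin probabilities proportional to
#' `(r_b/r_last)^alpha * exp(-u_true(b) / eta_rt)`, sampled as one
#' multinomial draw. The last-bin energy must be zero (the boundary
#' condition the derivation pins down); otherwise an error is raised.
#' Used to check that [derive_potential()] recovers a known energy
#' function from finite counts.
#'
#' @param u_true Numeric vector of per-bin energies (`eta_rt` units),
#'   last element 0.
#' @param n_samples Total pair count to distribute.
#' @param params A [dfire_params()].
#' @param seed Integer seed.
#' @return Integer vector of per-bin counts.
#' @export
sample_counts_from_potential <- function(u_true, n_samples,
                                         params = dfire_params(),
                                         seed = 1L) {
  nb <- params$scheme$n_bins
  stopifnot(length(u_true) == nb, n_samples >= 1)
  if (u_true[nb] != 0) {
    stop_dfire("u_true must be 0 in the last bin (cutoff boundary condition)",
               "dfire_domain")
  }
  mids <- params$scheme$midpoints
  p <- (mids / mids[nb])^params$alpha * exp(-u_true / params$eta_rt)
  withr::with_seed(seed, as.integer(rmultinom(1, n_samples, p)))
}

#' Generate a labelled synthetic screening set
#'
#' Active scores are `Normal(effect, 1)`, decoy scores `Normal(0, 1)` —
#' the standard two-normal model, for which the expected ROC AUC is
#' `pnorm(effect / sqrt(2))`. The default 50 decoys per active follows
#' common benchmark practice.
#'
#' @param n_actives,n_decoys Set sizes (>= 1).
#' @param effect Mean score separation between actives and decoys.
#' @param seed Integer seed.
#' @return Tibble `ligand_id`, `score`, `is_active`.
#' @export
simulate_screening_set <- function(n_actives = 20L, n_decoys = 1000L,
                                   effect = 1, seed = 1L) {
  stopifnot(n_actives >= 1L, n_decoys >= 1L)
  withr::with_seed(seed, tibble(
    ligand_id = c(paste0("active_", seq_len(n_actives)),
                  paste0("decoy_", seq_len(n_decoys))),
    score = c(rnorm(n_actives, effect, 1), rnorm(n_decoys, 0, 1)),
    is_active = rep(c(TRUE, FALSE), c(n_actives, n_decoys))
  ))
}
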