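#' Score a protein-ligand complex
#'
#' Sums the potential over every (protein heavy atom, ligand heavy atom)
#' pair closer than the cutoff: pairs at or beyond `r_cut` contribute
#' exactly zero. Untypeable receptor atoms and non-scoreable ligand
#' atoms (hydrogens, untypeable types) are skipped and counted. The
#' reported `score` is the negated energy, so higher score means
#' stronger predicted binding; `energy` is the raw sum in `eta_rt`
#' units.
#'
#' @param receptor Atom tibble (see [read_pdb_chain()]).
#' @param pose Single-pose tibble (see [read_mol2_poses()],
#'   [split_poses()]); must have `sybyl`, `x`, `y`, `z` (typing columns
#'   are recomputed if absent).
#' @param potential A `dfire_potential`.
#' @param map `type_map` used for any re-typing.
#' @param complex_id,pose_id Identifiers carried into the result;
#'   default from the pose.
#' @return One-row tibble: `complex_id`, `pose_id`, `energy`, `score`,
#'   `n_pairs`, `n_skipped_receptor`, `n_skipped_ligand`.
#' @export
score_complex <- function(receptor, pose, potential,
                          map = default_type_map(),
                          complex_id = NULL, pose_id = NULL) {
  stopifnot(inherits(potential, "dfire_potential"))
  scheme <- potential$params$scheme

  rec <- type_protein_atoms(receptor)
  n_skip_r <- sum(is.na(rec$type_index))
  rec <- filter(rec, !is.na(.data$type_index))

  if (!all(c("status", "type_index") %in% names(pose))) {
    ty <- type_ligand_atoms(pose$sybyl, map)
    pose$status <- ty$status
    pose$type_index <- ty$type_index
  }
  n_skip_l <- sum(pose$status != "typed")
  lig <- filter(pose, .data$status == "typed")
  if (nrow(lig) == 0L) {
    stop_dfire("no scoreable (typed heavy) ligand atoms", "dfire_domain")
  }

  pid <- pose_id %||% (if ("pose_id" %in% names(pose)) pose$pose_id[1] else "pose_1")
  cid <- complex_id %||% (if ("molecule_name" %in% names(pose)) pose$molecule_name[1] else "complex")

  energy <- 0
  n_pairs <- 0L
  if (nrow(rec) > 0L) {
    d <- cross_dist(cbind(rec$x, rec$y, rec$z), cbind(lig$x, lig$y, lig$z))
    keep <- d < scheme$r_cut
    if (any(keep)) {
      pr <- which(keep, arr.ind = TRUE)
      idx <- cbind(rec$type_index[pr[, 1]], lig$type_index[pr[, 2]],
                   bin_index(d[keep], scheme))
      energy <- sum(potential$energies[idx])
      n_pairs <- nrow(pr)
    }
  }
  tibble(complex_id = cid, pose_id = pid, energy = energy, score = -energy,
         n_pairs = n_pairs, n_skipped_receptor = n_skip_r,
         n_skipped_ligand = n_skip_l)
}

#' Score every pose in a multi-pose table
#'
#' @param receptor Atom tibble.
#' @param poses Multi-pose tibble from [read_mol2_poses()].
#' @param potential A `dfire_potential`.
#' @param map A `type_map`.
#' @param complex_id Identifier for the complex.
#' @return Tibble with one row per pose, in file order.
#' @export
score_poses <- function(receptor, poses, potential,
                        map = default_type_map(), complex_id = NULL) {
  purrr::map_dfr(split_poses(poses), score_complex,
                 receptor = receptor, potential = potential, map = map,
                 complex_id = complex_id)
}

#' Best pose of a scored set
#'
#' Picks the minimum-energy (maximum-score) pose; exact ties go to the
#' earliest pose in input order. Used for best-of-n rescoring, where a
#' complex's predicted affinity is the best score among its docked
#' poses.
#'
#' @param scores Tibble of scored poses for one complex (as from
#'   [score_poses()]).
#' @return The winning row.
#' @export
best_pose <- function(scores) {
  if (is.null(scores) || nrow(scores) == 0L) {
    stop_dfire("no poses to choose from", "dfire_domain")
  }
  if (length(unique(scores$complex_id)) != 1L) {
    stop_dfire("best_pose expects poses of a single complex", "dfire_domain")
  }
  scores[which.min(scores$energy), ]
}

#' Heavy-atom RMSD between two poses of the same molecule
#'
#' Root-mean-square coordinate deviation over heavy atoms, without
#' superposition: docked poses share the receptor frame, so rigid
#' alignment would hide placement error. Atoms must correspond
#' one-to-one in order; no symmetry (automorphism) correction is
#' applied.
#'
#' @param pose,reference Single-pose tibbles with matching heavy atoms.
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(pose, reference) {
  hv <- function(p) {
    if (!"status" %in% names(p)) {
      p$status <- type_ligand_atoms(p$sybyl)$status
    }
    filter(p, .data$status != "ignored")
  }
  a <- hv(pose)
  b <- hv(reference)
  if (nrow(a) != nrow(b)) {
    stop_dfire(sprintf("heavy-atom count mismatch: %d vs %d",
                       nrow(a), nrow(b)), "dfire_domain")
  }
  if (nrow(a) == 0L) stop_dfire("no heavy atoms", "dfire_domain")
  sqrt(mean((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2))
}
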