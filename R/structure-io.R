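#' Read one protein chain from a PDB file
#'
#' Parses with [bio3d::read.pdb()] (model 1 for multi-model files) and
#' applies the receptor-side filtering policy:
#' * heavy atoms only (hydrogen/deuterium dropped);
#' * `ATOM` records of the requested chain; `HETATM` excluded except
#'   selenomethionine (`MSE`), so waters and ligands never enter;
#' * alternate locations resolved per atom by highest occupancy, ties by
#'   altloc `"A"`, then file order.
#'
#' @param path Path to a PDB file.
#' @param chain_id Single chain identifier; if `NULL` and the file holds
#'   exactly one chain, that chain is used.
#' @return A tibble with columns `residue_name`, `atom_name`,
#'   `residue_seq` (author numbering with any insertion code appended),
#'   `chain_id`, `x`, `y`, `z`, `occupancy`, `element`.
#' @examples
#' \dontrun{
#' rec <- read_pdb_chain("receptor.pdb", "A")
#' }
#' @export
read_pdb_chain <- function(path, chain_id = NULL) {
  if (!file.exists(path)) {
    stop_dfire(paste0("PDB file not found: ", path), "dfire_io")
  }
  pdb <- suppressWarnings(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE))
  at <- as_tibble(pdb$atom)

  chains <- sort(unique(at$chain[at$type == "ATOM" | at$resid == "MSE"]))
  if (is.null(chain_id)) {
    if (length(chains) != 1L) {
      stop_dfire(paste0("chain_id required; file has chains: ",
                        paste(chains, collapse = ", ")), "dfire_io")
    }
    chain_id <- chains
  }
  if (!chain_id %in% at$chain) {
    stop_dfire(paste0("chain '", chain_id, "' not present; available: ",
                      paste(chains, collapse = ", ")), "dfire_missing_chain")
  }

  at <- at |>
    filter(.data$chain == chain_id,
           .data$type == "ATOM" | .data$resid == "MSE",
           !.data$elesy %in% c("H", "D")) |>
    mutate(file_order = row_number(),
           insert = ifelse(is.na(.data$insert), "", .data$insert),
           alt = ifelse(is.na(.data$alt), "", .data$alt),
           o = ifelse(is.na(.data$o), 1, .data$o))

  # altloc policy: per (residue, atom) keep highest occupancy, ties "A",
  # then first in file
  at <- at |>
    arrange(.data$file_order) |>
    group_by(.data$resno, .data$insert, .data$resid, .data$elety) |>
    arrange(desc(.data$o), .data$alt != "A", .data$file_order,
            .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    arrange(.data$file_order)

  tibble(
    residue_name = at$resid,
    atom_name = at$elety,
    residue_seq = paste0(at$resno, at$insert),
    chain_id = at$chain,
    x = at$x, y = at$y, z = at$z,
    occupancy = at$o,
    element = at$elesy
  )
}

#' Read ligand poses from a (possibly multi-molecule) mol2 file
#'
#' Each `@<TRIPOS>MOLECULE` block becomes one pose, in file order, with
#' `pose_id` `"<name>_<block>"`. Hydrogens are retained in the table but
#' are flagged by `status = "ignored"` and never scored; heavy atoms with
#' SYBYL types outside the canonical 11 resolve through the type map's
#' fallbacks.
#'
#' @param path Path to a SYBYL mol2 file.
#' @param map A `type_map` used to type atoms; defaults to the bundled one.
#' @return A tibble with columns `pose_id`, `molecule_name`, `atom_name`,
#'   `sybyl`, `x`, `y`, `z`, `status`, `type_index`; zero rows for an
#'   empty file.
#' @export
read_mol2_poses <- function(path, map = default_type_map()) {
  if (!file.exists(path)) {
    stop_dfire(paste0("mol2 file not found: ", path), "dfire_io")
  }
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
    return(tibble(pose_id = character(), molecule_name = character(),
                  atom_name = character(), sybyl = character(),
                  x = double(), y = double(), z = double(),
                  status = character(), type_index = integer()))
  }
  mols <- suppressWarnings(bio3d::read.mol2(path))
  if (inherits(mols, "mol2")) {
    # identical-topology multi-pose files come back as one molecule with
    # one xyz row per pose; expand back into per-pose records
    xyz <- mols$xyz
    mols <- lapply(seq_len(nrow(xyz)), function(i) {
      m <- mols
      m$atom$x <- xyz[i, c(TRUE, FALSE, FALSE)]
      m$atom$y <- xyz[i, c(FALSE, TRUE, FALSE)]
      m$atom$z <- xyz[i, c(FALSE, FALSE, TRUE)]
      m
    })
  }

  purrr::imap_dfr(mols, function(m, i) {
    if (is.null(m$atom) || nrow(m$atom) == 0L) {
      stop_dfire(paste0("mol2 block ", i, " has no ATOM section: ", path),
                 "dfire_io")
    }
    ty <- type_ligand_atoms(m$atom$elety, map)
    tibble(
      pose_id = paste0(m$name, "_", i),
      molecule_name = m$name,
      atom_name = m$atom$elena,
      sybyl = m$atom$elety,
      x = m$atom$x, y = m$atom$y, z = m$atom$z,
      status = ty$status,
      type_index = ty$type_index
    )
  })
}

#' Split a pose table into a list of single poses
#'
#' @param poses A tibble from [read_mol2_poses()].
#' @return Named list of single-pose tibbles, in first-appearance order.
#' @export
split_poses <- function(poses) {
  split(poses, factor(poses$pose_id, levels = unique(poses$pose_id)))
}
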