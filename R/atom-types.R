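# Heavy-atom names (PDB v3) for the 20 standard residues, backbone first.
# Jointly (residue, atom) these are the 167 residue-specific protein atom
# types the potential is indexed by.
.backbone <- c("N", "CA", "C", "O")
.residue_atoms <- list(
  ALA = c(.backbone, "CB"),
  ARG = c(.backbone, "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c(.backbone, "CB", "CG", "OD1", "ND2"),
  ASP = c(.backbone, "CB", "CG", "OD1", "OD2"),
  CYS = c(.backbone, "CB", "SG"),
  GLN = c(.backbone, "CB", "CG", "CD", "OE1", "NE2"),
  GLU = c(.backbone, "CB", "CG", "CD", "OE1", "OE2"),
  GLY = .backbone,
  HIS = c(.backbone, "CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c(.backbone, "CB", "CG1", "CG2", "CD1"),
  LEU = c(.backbone, "CB", "CG", "CD1", "CD2"),
  LYS = c(.backbone, "CB", "CG", "CD", "CE", "NZ"),
  MET = c(.backbone, "CB", "CG", "SD", "CE"),
  PHE = c(.backbone, "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c(.backbone, "CB", "CG", "CD"),
  SER = c(.backbone, "CB", "OG"),
  THR = c(.backbone, "CB", "OG1", "CG2"),
  TRP = c(.backbone, "CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3",
          "CZ2", "CZ3", "CH2"),
  TYR = c(.backbone, "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c(.backbone, "CB", "CG1", "CG2")
)

# The 11 canonical SYBYL mol2 targets of the protein->mol2 collapse.
.canonical_mol2 <- c("C.3", "C.2", "C.ar", "N.3", "N.2", "N.ar", "N.am",
                     "O.3", "O.2", "O.co2", "S.3")

# SYBYL types treated as non-interacting and silently skipped
# (hydrogens, dummies, lone pairs).
.ignored_sybyl <- c("H", "H.spc", "H.t3p", "D", "Du", "Du.C", "LP")

#' Residue-specific protein atom-type alphabet
#'
#' Enumerates the 167 heavy-atom types of the 20 standard amino acids.
#' A protein atom type is the joint identity (residue name, PDB v3 atom
#' name), so e.g. `GLU.CB` and `LYS.CE` are distinct types even though
#' both are sp3 carbons. Residues are ordered alphabetically and atoms in
#' canonical PDB order (backbone N, CA, C, O, then side chain), so the
#' `index` column is stable across sessions.
#'
#' @return A tibble with columns `index` (1..167), `residue_name`,
#'   `atom_name`.
#' @examples
#' protein_alphabet()
#' @export
protein_alphabet <- function() {
  res <- names(.residue_atoms)
  tb <- tibble(
    residue_name = rep(res, lengths(.residue_atoms)),
    atom_name = unlist(.residue_atoms, use.names = FALSE)
  )
  if (nrow(tb) != 167L || anyDuplicated(paste(tb$residue_name, tb$atom_name))) {
    stop_dfire("bundled protein atom-type table is malformed", "dfire_config")
  }
  mutate(tb, index = row_number(), .before = 1)
}

#' Canonical ligand (SYBYL mol2) atom-type alphabet
#'
#' The 11 SYBYL mol2 atom types that protein atom types collapse onto and
#' that ligand atoms are scored with: sp3/sp2/aromatic carbon, sp3/sp2/
#' aromatic/amide nitrogen, sp3/sp2/carboxylate oxygen and sp3 sulfur.
#'
#' @return A tibble with columns `index` (1..11) and `sybyl_name`.
#' @export
ligand_alphabet <- function() {
  tibble(index = seq_along(.canonical_mol2), sybyl_name = .canonical_mol2)
}

# "RES ATOM" keys in alphabet order, used for O(1) type lookup
.alphabet_keys <- function() {
  ab <- protein_alphabet()
  paste(ab$residue_name, ab$atom_name)
}

#' Read a protein/ligand atom-type map
#'
#' The type map has two parts: a total map from each of the 167 protein
#' atom types to one of the 11 canonical mol2 types (the collapse used
#' when converting protein-protein pair counts into protein-ligand
#' statistics), and a fallback map that resolves SYBYL types seen in
#' ligand files but absent from the canonical 11 (e.g. `P.3`, halogens,
#' metal ions) to their closest canonical type.
#'
#' The file format is plain text: `#` comments; protein lines
#' `RES ATOM MOL2TYPE`; fallback lines `SYBYL MOL2TYPE`. The map is
#' validated on load: the protein side must cover all 167 types exactly
#' once and its image must be exactly the 11 canonical types; fallbacks
#' must target canonical types only.
#'
#' @param path Path to a map file; defaults to the bundled map.
#' @return An object of class `type_map`.
#' @seealso [write_type_map()], [collapse_index()]
#' @export
read_type_map <- function(path = default_type_map_path()) {
  if (!file.exists(path)) {
    stop_dfire(paste0("type map file not found: ", path), "dfire_config")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "[[:space:]]+")
  nt <- lengths(toks)
  if (any(!nt %in% c(2L, 3L))) {
    bad <- which(!nt %in% c(2L, 3L))[1]
    stop_dfire(paste0("malformed type-map line: '", lines[bad], "'"),
               "dfire_config")
  }
  prot <- toks[nt == 3L]
  fall <- toks[nt == 2L]

  protein <- setNames(
    vapply(prot, `[[`, "", 3L),
    vapply(prot, function(t) paste(t[[1]], t[[2]]), "")
  )
  fallback <- setNames(vapply(fall, `[[`, "", 2L),
                       vapply(fall, `[[`, "", 1L))

  keys <- .alphabet_keys()
  missing <- setdiff(keys, names(protein))
  extra <- setdiff(names(protein), keys)
  if (length(missing) || length(extra) || anyDuplicated(names(protein))) {
    stop_dfire(paste0(
      "protein map must cover the 167-type alphabet exactly once; missing: ",
      paste(head(missing, 3), collapse = ", "), "; unknown: ",
      paste(head(extra, 3), collapse = ", ")), "dfire_config")
  }
  img <- sort(unique(unname(protein)))
  if (!identical(img, sort(.canonical_mol2))) {
    stop_dfire(paste0(
      "protein map image must be exactly the 11 canonical mol2 types, got: ",
      paste(img, collapse = ", ")), "dfire_config")
  }
  if (any(!fallback %in% .canonical_mol2)) {
    stop_dfire("ligand fallback targets must be canonical mol2 types",
               "dfire_config")
  }

  map <- structure(
    list(protein = protein[keys],    # alphabet order
         fallback = fallback[order(names(fallback))]),
    class = "type_map")
  map$hash <- .type_map_hash(map)
  map
}

#' @rdname read_type_map
#' @export
default_type_map_path <- function() {
  system.file("extdata", "type_map.txt", package = "dfirescore",
              mustWork = TRUE)
}

#' @rdname read_type_map
#' @export
default_type_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_type_map()
    cache
  }
})

# canonical serialized form; writer output and hash input
.type_map_text <- function(map) {
  c(paste(names(map$protein), unname(map$protein)),
    paste(names(map$fallback), unname(map$fallback)))
}

.type_map_hash <- function(map) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(.type_map_text(map), f)
  unname(tools::md5sum(f))
}

#' Write a type map in canonical form
#'
#' Serializes a [read_type_map()] object deterministically (protein
#' entries in alphabet order, fallbacks sorted), so write/read/write
#' round-trips are byte-identical.
#'
#' @param map A `type_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_type_map <- function(map, path) {
  stopifnot(inherits(map, "type_map"))
  writeLines(.type_map_text(map), path)
  invisible(path)
}

#' @export
print.type_map <- function(x, ...) {
  cat("<type_map> 167 protein atom types -> 11 mol2 types; ",
      length(x$fallback), " ligand fallbacks; hash ", x$hash, "\n", sep = "")
  invisible(x)
}

#' Assign residue-specific types to protein atoms
#'
#' Adds a `type_index` column (position in [protein_alphabet()], or `NA`
#' for atoms outside the standard-residue alphabet). Two aliases are
#' applied first: a terminal `OXT` is typed as its residue's backbone
#' `O`, and selenomethionine (`MSE`) is typed as `MET` with `SE` -> `SD`.
#' Non-standard residues and unknown atom names are left untypeable
#' (`NA`); callers decide whether to skip or abort.
#'
#' @param atoms A data frame with `residue_name` and `atom_name` columns
#'   (e.g. from [read_pdb_chain()]).
#' @return `atoms` as a tibble with an added integer `type_index`.
#' @examples
#' type_protein_atoms(data.frame(residue_name = "ASP", atom_name = "OD1"))
#' @export
type_protein_atoms <- function(atoms) {
  atoms <- as_tibble(atoms)
  res <- toupper(trimws(atoms$residue_name))
  atm <- toupper(trimws(atoms$atom_name))
  # aliases: MSE -> MET (SE -> SD); OXT -> backbone O
  is_mse <- res == "MSE"
  res[is_mse] <- "MET"
  atm[is_mse & atm == "SE"] <- "SD"
  atm[atm == "OXT"] <- "O"
  idx <- match(paste(res, atm), .alphabet_keys())
  mutate(atoms, type_index = as.integer(idx))
}

#' Assign canonical mol2 types to ligand atoms
#'
#' Resolves SYBYL type strings from a mol2 ATOM section against the
#' 11-type canonical alphabet. Canonical types map to themselves;
#' non-canonical heavy types resolve through the map's fallback table
#' (e.g. `P.3` scores as `S.3`); hydrogens, dummies and lone pairs are
#' flagged `"ignored"`; anything else is `"untypeable"`.
#'
#' @param sybyl Character vector of SYBYL type strings.
#' @param map A `type_map`; defaults to the bundled one.
#' @return A tibble with columns `sybyl`, `status`
#'   (`"typed"`/`"ignored"`/`"untypeable"`) and integer `type_index`
#'   (`NA` unless typed).
#' @examples
#' type_ligand_atoms(c("N.am", "P.3", "H", "Xx"))
#' @export
type_ligand_atoms <- function(sybyl, map = default_type_map()) {
  sybyl <- trimws(sybyl)
  target <- ifelse(sybyl %in% .canonical_mol2, sybyl,
                   unname(map$fallback[sybyl]))
  idx <- match(target, .canonical_mol2)
  status <- dplyr::case_when(
    sybyl %in% .ignored_sybyl ~ "ignored",
    !is.na(idx) ~ "typed",
    .default = "untypeable"
  )
  tibble(sybyl = sybyl, status = status,
         type_index = ifelse(status == "typed", idx, NA_integer_))
}

#' Collapse protein atom types onto mol2 types
#'
#' The surjection at the heart of the protein-only training trick:
#' every residue-specific protein type stands in for one of the 11 mol2
#' ligand types, so pair statistics gathered between protein atoms can be
#' reused as protein-ligand statistics.
#'
#' @param protein_index Integer vector of protein type indices (1..167).
#' @param map A `type_map`.
#' @return Integer vector of ligand type indices (1..11).
#' @examples
#' ab <- protein_alphabet()
#' i <- ab$index[ab$residue_name == "GLU" & ab$atom_name == "CB"]
#' ligand_alphabet()$sybyl_name[collapse_index(i)]  # "C.3"
#' @export
collapse_index <- function(protein_index, map = default_type_map()) {
  stopifnot(all(protein_index >= 1L & protein_index <= 167L))
  match(unname(map$protein[protein_index]), .canonical_mol2)
}
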