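# hand-built PDB text, fixed columns
pdb_line <- function(type = "ATOM", eleno, name, alt = " ", resid, chain,
                     resno, x, y, z, occ = 1, elesy) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, eleno, name, alt, resid, chain, resno, x, y, z, occ, 0, elesy)
}

test_that("read_pdb_chain drops hydrogens, waters and foreign HETATMs", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(eleno = 1, name = " N  ", resid = "GLY", chain = "A", resno = 1,
             x = 0, y = 0, z = 0, elesy = "N"),
    pdb_line(eleno = 2, name = " CA ", resid = "GLY", chain = "A", resno = 1,
             x = 1.5, y = 0, z = 0, elesy = "C"),
    pdb_line(eleno = 3, name = " C  ", resid = "GLY", chain = "A", resno = 1,
             x = 2.2, y = 1.1, z = 0, elesy = "C"),
    pdb_line(eleno = 4, name = " O  ", resid = "GLY", chain = "A", resno = 1,
             x = 3.4, y = 1.1, z = 0.2, elesy = "O"),
    pdb_line(eleno = 5, name = " H  ", resid = "GLY", chain = "A", resno = 1,
             x = 0.1, y = -0.9, z = 0, elesy = "H"),
    pdb_line(eleno = 6, name = " HA ", resid = "GLY", chain = "A", resno = 1,
             x = 1.6, y = -0.5, z = 0.9, elesy = "H"),
    pdb_line("HETATM", eleno = 7, name = " O  ", resid = "HOH", chain = "A",
             resno = 90, x = 9, y = 9, z = 9, elesy = "O"),
    pdb_line("HETATM", eleno = 8, name = " C1 ", resid = "LIG", chain = "A",
             resno = 91, x = 8, y = 8, z = 8, elesy = "C"),
    "END"), f)
  rec <- read_pdb_chain(f, "A")
  expect_equal(nrow(rec), 4L)
  expect_equal(rec$atom_name, c("N", "CA", "C", "O"))
  expect_equal(rec$element, c("N", "C", "C", "O"))
})

test_that("selenomethionine HETATMs are kept and typeable", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line("HETATM", eleno = 1, name = " N  ", resid = "MSE", chain = "A",
             resno = 1, x = 0, y = 0, z = 0, elesy = "N"),
    pdb_line("HETATM", eleno = 2, name = " CA ", resid = "MSE", chain = "A",
             resno = 1, x = 1.5, y = 0, z = 0, elesy = "C"),
    pdb_line("HETATM", eleno = 3, name = "SE  ", resid = "MSE", chain = "A",
             resno = 1, x = 3, y = 1, z = 1, elesy = "SE"),
    "END"), f)
  rec <- read_pdb_chain(f, "A")
  expect_equal(nrow(rec), 3L)
  typed <- type_protein_atoms(rec)
  expect_false(anyNA(typed$type_index))
})

test_that("alternate locations resolve by occupancy, then altloc A, then order", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(eleno = 1, name = " CA ", alt = "A", resid = "ALA", chain = "A",
             resno = 1, x = 1, y = 0, z = 0, occ = 0.6, elesy = "C"),
    pdb_line(eleno = 2, name = " CA ", alt = "B", resid = "ALA", chain = "A",
             resno = 1, x = 9, y = 0, z = 0, occ = 0.4, elesy = "C"),
    # tie at same occupancy: B first in file, but A preferred
    pdb_line(eleno = 3, name = " CB ", alt = "B", resid = "ALA", chain = "A",
             resno = 1, x = 7, y = 0, z = 0, occ = 0.5, elesy = "C"),
    pdb_line(eleno = 4, name = " CB ", alt = "A", resid = "ALA", chain = "A",
             resno = 1, x = 2, y = 0, z = 0, occ = 0.5, elesy = "C"),
    # higher occupancy wins even against altloc A
    pdb_line(eleno = 5, name = " N  ", alt = "A", resid = "ALA", chain = "A",
             resno = 1, x = 5, y = 0, z = 0, occ = 0.3, elesy = "N"),
    pdb_line(eleno = 6, name = " N  ", alt = "C", resid = "ALA", chain = "A",
             resno = 1, x = 3, y = 0, z = 0, occ = 0.7, elesy = "N"),
    "END"), f)
  rec <- read_pdb_chain(f, "A")
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$x[rec$atom_name == "CA"], 1)
  expect_equal(rec$x[rec$atom_name == "CB"], 2)
  expect_equal(rec$x[rec$atom_name == "N"], 3)
})

test_that("a missing chain errors and names the available chains", {
  f <- withr::local_tempfile(fileext = ".pdb")
  simulate_protein(3, seed = 5, path = f)
  err <- expect_error(read_pdb_chain(f, "Z"), class = "dfire_missing_chain")
  expect_match(conditionMessage(err), "A")
  # single-chain files do not need an explicit chain id
  expect_equal(nrow(read_pdb_chain(f)), nrow(read_pdb_chain(f, "A")))
})

test_that("mol2 reading: pose per block, hydrogens flagged, empty file", {
  lig <- simulate_ligand(5, seed = 11, name = "m")
  hyd <- lig[rep(1, 6), ]
  hyd$sybyl <- "H"
  hyd$atom_name <- paste0("H", 1:6)
  one <- dplyr::bind_rows(lig, hyd)
  f <- withr::local_tempfile(fileext = ".mol2")
  write_mol2_poses(one, f)
  got <- read_mol2_poses(f)
  expect_equal(nrow(got), 11L)
  expect_equal(sum(got$status == "typed"), 5L)
  expect_equal(sum(got$status == "ignored"), 6L)

  # ten blocks -> ten poses with _1.._10 suffixes, file order
  many <- purrr::map_dfr(1:10, function(i)
    perturb_pose(lig, shift = c(i, 0, 0), pose_id = paste0("m_", i)))
  f10 <- withr::local_tempfile(fileext = ".mol2")
  write_mol2_poses(many, f10)
  got10 <- read_mol2_poses(f10)
  expect_equal(unique(got10$pose_id), paste0("m_", 1:10))
  expect_equal(length(split_poses(got10)), 10L)

  fe <- withr::local_tempfile(fileext = ".mol2")
  file.create(fe)
  expect_equal(nrow(read_mol2_poses(fe)), 0L)
})

test_that("reading is deterministic and fixtures round-trip coordinates", {
  fp <- withr::local_tempfile(fileext = ".pdb")
  fl <- withr::local_tempfile(fileext = ".mol2")
  prot <- simulate_protein(12, seed = 9, path = fp)
  lig <- simulate_ligand(7, seed = 9, path = fl)
  r1 <- read_pdb_chain(fp, "A")
  r2 <- read_pdb_chain(fp, "A")
  expect_identical(r1, r2)
  expect_lt(max(abs(r1$x - prot$x)), 1e-3 + 1e-12)  # PDB fixed-width
  expect_lt(max(abs(r1$y - prot$y)), 1e-3 + 1e-12)
  expect_lt(max(abs(r1$z - prot$z)), 1e-3 + 1e-12)
  m1 <- read_mol2_poses(fl)
  expect_identical(m1, read_mol2_poses(fl))
  expect_lt(max(abs(m1$x - lig$x)), 1e-3 + 1e-12)
})
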