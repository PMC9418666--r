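test_that("receptor PDB round trip preserves names, numbering and coordinates", {
  tc <- generate_toy_complex(complex_spec(seed = 1))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_receptor_pdb(tc$receptor, path)
  rec <- read_receptor(path)
  expect_equal(rec$atoms$atom_name, tc$receptor$atoms$atom_name)
  expect_equal(rec$atoms$residue_number, tc$receptor$atoms$residue_number)
  expect_equal(rec$atoms$residue_name, tc$receptor$atoms$residue_name)
  expect_equal(atoms_xyz <- as.matrix(rec$atoms[, c("x", "y", "z")]),
               as.matrix(tc$receptor$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("an aspartate numbered 113 exposes OD1 and OD2 through the residue index", {
  tc <- generate_toy_complex(complex_spec(seed = 1))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_receptor_pdb(tc$receptor, path)
  rec <- read_receptor(path)
  asp <- residue_atoms(rec, "A", 113)
  expect_true(all(c("OD1", "OD2") %in% asp$atom_name))
  expect_identical(unique(asp$residue_name), "ASP")
})

test_that("water-only and unreadable PDB inputs raise parse errors", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A 501       0.000   0.000   0.000  1.00  0.00           O",
    "END"), path)
  expect_error(read_receptor(path), "no protein atoms")
  expect_error(read_receptor(file.path(tempdir(), "nope.pdb")), "not found")
})

test_that("SDF round trip preserves identity, charges and aromatic flags", {
  tc1 <- generate_toy_complex(complex_spec(planted = "aromatic",
                                           ligand_id = "lig 752",
                                           pose_number = 4, seed = 2))
  tc2 <- generate_toy_complex(complex_spec(ligand_id = "lig 752",
                                           pose_number = 5, seed = 3))
  path <- withr::local_tempfile(fileext = ".sdf")
  write_poses_sdf(list(tc1$pose, tc2$pose), path)
  poses <- read_poses(path)
  expect_length(poses, 2)
  expect_identical(poses[[1]]$ligand_id, "lig 752")
  expect_identical(poses[[1]]$pose_number, 4L)
  expect_identical(sample_id(poses[[1]]), "lig 752_04")
  expect_identical(poses[[2]]$pose_number, 5L)
  # formal charge of the planted ammonium nitrogen survives
  expect_identical(sum(poses[[2]]$atoms$formal_charge), 1L)
  # aromatic bond flags survive
  expect_identical(sum(poses[[1]]$bonds$aromatic), 6L)
  expect_equal(as.matrix(poses[[1]]$atoms[, c("x", "y", "z")]),
               as.matrix(tc1$pose$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("empty and malformed SDF inputs are handled explicitly", {
  empty <- withr::local_tempfile(fileext = ".sdf")
  writeLines(character(0), empty)
  expect_warning(poses <- read_poses(empty), "empty")
  expect_length(poses, 0)

  # a record whose title line is blank is flagged by index
  untitled <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(
    "", "  made by hand", "",
    "  1  0  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "M  END", "$$$$"), untitled)
  expect_error(suppressWarnings(read_poses(untitled)), "1")

  badtitle <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(
    "no pose suffix", "  made by hand", "",
    "  2  1  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0",
    "M  END", "$$$$"), badtitle)
  expect_error(read_poses(badtitle), "poseNumber")
})

test_that("ligand atom roles follow element, charge and bonding", {
  tc <- generate_toy_complex(complex_spec(
    planted = c("aromatic", "hydrophobic"), seed = 4))
  pose <- tc$pose
  roles_of <- function(elem, charge = NULL) {
    sel <- pose$atoms$element == elem
    if (!is.null(charge)) sel <- sel & pose$atoms$formal_charge == charge
    pose$atoms$roles[sel]
  }
  # protonated amine: cation and donor
  nplus <- roles_of("N", 1L)[[1]]
  expect_true(all(c("cation", "donor") %in% nplus))
  # hydroxyl-like oxygen: donor and acceptor
  ohyd <- roles_of("O")[[1]]
  expect_true(all(c("donor", "acceptor") %in% ohyd))
  # benzene carbons: aromatic and hydrophobe
  ring <- pose$atoms$roles[vapply(pose$atoms$roles, function(r)
    "aromatic" %in% r, logical(1))]
  expect_length(ring, 6)
  expect_true(all(vapply(ring, function(r) "hydrophobe" %in% r, logical(1))))
})

test_that("receptor templates give Asp carboxylate oxygens anion + acceptor", {
  rec <- aifp:::.build_toy_receptor()
  od2 <- rec$atoms$roles[rec$atoms$residue_number == 113 &
                           rec$atoms$atom_name == "OD2"][[1]]
  expect_true(all(c("anion", "acceptor") %in% od2))
  nz_absent <- rec$atoms$atom_name[rec$atoms$residue_number == 113]
  expect_false("NZ" %in% nz_absent)
})

test_that("unknown residues fall back to element-only roles with a warning", {
  atoms <- aifp:::new_atom_table(
    atom_name = c("X1", "X2"), element = c("O", "N"),
    residue_name = "XYZ", residue_number = 7L, chain_id = "A",
    xyz = rbind(c(0, 0, 0), c(2, 0, 0)))
  rec <- aifp:::new_receptor(atoms)
  expect_warning(rec <- assign_atom_roles(rec), "unknown residue")
  expect_identical(rec$atoms$roles[[1]], "acceptor")
  expect_identical(rec$atoms$roles[[2]], "donor")
})

test_that("role assignment is a pure function of its input", {
  tc <- generate_toy_complex(complex_spec(seed = 6))
  again <- assign_atom_roles(tc$pose)
  expect_identical(tc$pose$atoms$roles, again$atoms$roles)
  expect_identical(assign_atom_roles(tc$receptor)$atoms$roles,
                   tc$receptor$atoms$roles)
})
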