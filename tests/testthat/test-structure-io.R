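test_that("a hand-written PDB parses field-for-field", {
  path <- write_three_atom_pdb(tempfile(fileext = ".pdb"))
  s <- read_structure(path)
  expect_equal(nrow(s), 3)
  expect_equal(s$name, c("N", "CA", "C"))
  expect_equal(s$element, c("N", "C", "C"))
  expect_equal(s$res_name, rep("LEU", 3))
  expect_equal(s$chain_id, rep("P", 3))
  expect_equal(s$x, c(11.104, 12.560, 13.120), tolerance = 1e-9)
  expect_equal(s$y, c(13.207, 13.300, 14.510), tolerance = 1e-9)
  expect_equal(s$b_iso, c(30.10, 31.20, 32.30), tolerance = 1e-9)
  expect_equal(s$occupancy, rep(1, 3))
})

test_that("unit-cell and resolution header fields are exposed", {
  path <- write_three_atom_pdb(tempfile(fileext = ".pdb"))
  h <- structure_header(read_structure(path))
  expect_equal(h$cell_a, 56.96)
  expect_equal(h$cell_b, 121.29)
  expect_equal(h$cell_c, 68.96)
  expect_equal(c(h$cell_alpha, h$cell_beta, h$cell_gamma), c(90, 90, 90))
  expect_equal(h$space_group, "P 21 21 21")
  expect_equal(h$resolution, 1.95)
})

test_that("an atom-free file yields an empty model with a warning", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c("HEADER    NOTHING HERE", "END"), path)
  expect_warning(s <- read_structure(path), "no atom records")
  expect_equal(nrow(s), 0)
})

test_that("PDB write/read round trip preserves coordinates at format precision", {
  pep <- build_peptide("LSGSA", phi = c(0, -60, 80, -120, -60),
                       psi = c(120, 120, 0, 130, -40))
  path <- tempfile(fileext = ".pdb")
  write_pdb(pep, path)
  back <- read_structure(path)
  expect_equal(back$name, pep$name)
  expect_equal(back$res_name, pep$res_name)
  expect_equal(as.matrix(back[, c("x", "y", "z")]),
               as.matrix(pep[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("multi-model files come back as ordered models", {
  pep <- build_peptide("AAA", phi = -120, psi = 120)
  traj <- make_jitter_traj(pep, sigma = 0.8, n_frames = 4, seed = 3)$trajectory
  path <- tempfile(fileext = ".pdb")
  write_pdb(traj_to_multimodel(traj), path)
  back <- read_trajectory(path)
  expect_equal(n_frames(back), 4)
  expect_equal(back$coords, traj$coords, tolerance = 1e-3)
})

test_that("mmCIF input parses atoms and header", {
  cif <- c(
    "data_FIX",
    "_cell.length_a   56.960",
    "_cell.length_b   121.290",
    "_cell.length_c   68.960",
    "_cell.angle_alpha 90.00",
    "_cell.angle_beta  90.00",
    "_cell.angle_gamma 90.00",
    "_symmetry.space_group_name_H-M \"P 21 21 21\"",
    "_refine.ls_d_res_high 1.95",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . LEU A 1 1 ? 1.000 2.000 3.000 1.00 20.00 ? 1 LEU P N 1",
    "ATOM 2 C CA . LEU A 1 1 ? 2.400 2.100 3.100 1.00 21.00 ? 1 LEU P CA 1",
    "ATOM 3 C C . LEU A 1 1 ? 3.100 3.300 3.500 1.00 22.00 ? 1 LEU P C 1",
    "#")
  path <- tempfile(fileext = ".cif")
  writeLines(cif, path)
  s <- read_structure(path)
  expect_equal(nrow(s), 3)
  expect_equal(s$name, c("N", "CA", "C"))
  expect_equal(s$chain_id, rep("P", 3))
  expect_equal(s$x, c(1.0, 2.4, 3.1))
  h <- structure_header(s)
  expect_equal(h$cell_a, 56.96)
  expect_equal(h$resolution, 1.95)
})

test_that("altloc policies keep one conformer and are idempotent", {
  pep <- build_peptide("LS", phi = -120, psi = 120)
  dup <- tibble::as_tibble(pep)
  extra <- dup[dup$name == "CA" & dup$res_seq == 1, ]
  dup$alt_loc[dup$name == "CA" & dup$res_seq == 1] <- "A"
  dup$occupancy[dup$name == "CA" & dup$res_seq == 1] <- 0.6
  extra$alt_loc <- "B"; extra$occupancy <- 0.4; extra$serial <- 99L
  both <- pfrkit:::new_pfr_structure(rbind(dup, extra))

  kept <- apply_altloc_policy(both, "highest_occupancy")
  expect_equal(nrow(kept), nrow(pep))
  expect_equal(kept$alt_loc[kept$name == "CA" & kept$res_seq == 1], "A")

  # tie at 0.5/0.5 resolves alphabetically
  tie <- both
  tie$occupancy[tie$alt_loc %in% c("A", "B")] <- 0.5
  kept_tie <- apply_altloc_policy(tie, "highest_occupancy")
  expect_equal(kept_tie$alt_loc[kept_tie$name == "CA" & kept_tie$res_seq == 1], "A")

  first <- apply_altloc_policy(both, "first")
  expect_equal(first$alt_loc[first$name == "CA" & first$res_seq == 1], "A")

  expect_error(apply_altloc_policy(both, "strict"), "LEU")
  expect_identical(tibble::as_tibble(apply_altloc_policy(kept, "highest_occupancy")),
                   tibble::as_tibble(kept))

  # no altlocs: unchanged
  expect_identical(tibble::as_tibble(apply_altloc_policy(pep, "highest_occupancy")),
                   tibble::as_tibble(pep))
})

test_that("bfactor profile averages selected atoms and buckets by threshold", {
  pep <- build_peptide("ALAGS", phi = -120, psi = 120)
  atoms <- tibble::as_tibble(pep)
  atoms$b_iso <- c(30, 60, 90)[pmin(atoms$res_seq, 3)]
  atoms$b_iso[atoms$res_seq >= 4] <- 30
  s <- pfrkit:::new_pfr_structure(atoms)
  prof <- bfactor_profile(s, "P")
  expect_equal(prof$category[1:3], c("stable", "intermediate", "high-flex"))
  # oracle: direct mean of the selected atoms
  for (r in prof$res_seq) {
    expect_equal(prof$mean_b[prof$res_seq == r],
                 mean(atoms$b_iso[atoms$res_seq == r]))
  }
  expect_error(bfactor_profile(s, "Z"), "not found")

  # backbone selection averages only N, CA, C, O
  atoms2 <- atoms
  atoms2$b_iso[atoms2$name == "CB"] <- 500
  prof_bb <- bfactor_profile(pfrkit:::new_pfr_structure(atoms2), "P",
                             selection = "backbone")
  expect_true(all(prof_bb$mean_b < 100))
})
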