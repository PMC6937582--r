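two_atom_structure <- function(d, pep_name = "CB", pep_res = "ALA",
                               rec_name = "CB", rec_res = "ALA") {
  pfrkit:::new_pfr_structure(tibble::tibble(
    model = 1L, serial = 1:2, name = c(pep_name, rec_name),
    element = substr(c(pep_name, rec_name), 1, 1), alt_loc = "",
    res_name = c(pep_res, rec_res), chain_id = c("P", "R"),
    res_seq = c(1L, 2L), icode = "", x = c(0, d), y = 0, z = 0,
    occupancy = 1, b_iso = 20, het = FALSE))
}

test_that("atoms beyond the cutoff make no contact", {
  s <- two_atom_structure(5.0)
  expect_equal(nrow(find_contacts(s, "P", "R")), 0)
})

test_that("distance plus chemistry decides the vdW/H-bond split", {
  # serine hydroxyl donor 2.9 A from a backbone carbonyl acceptor: H-bond
  hb <- two_atom_structure(2.9, pep_name = "OG", pep_res = "SER",
                           rec_name = "O", rec_res = "GLY")
  p1 <- find_contacts(hb, "P", "R")
  expect_equal(nrow(p1), 1)
  expect_equal(p1$kind, "hbond")
  expect_equal(p1$distance, 2.9, tolerance = 1e-9)

  # carbon pair at 3.8 A: vdW even though under the H-bond cutoff range
  cb <- two_atom_structure(3.8)
  p2 <- find_contacts(cb, "P", "R")
  expect_equal(p2$kind, "vdw")

  # donor/acceptor chemistry but outside the H-bond cutoff: vdW
  far <- two_atom_structure(3.6, pep_name = "OG", pep_res = "SER",
                            rec_name = "O", rec_res = "GLY")
  expect_equal(find_contacts(far, "P", "R")$kind, "vdw")
})

test_that("planted scenes are recovered exactly (ledger and brute force)", {
  for (seed in 1:3) {
    n <- 4 + seed
    dists <- seq(2.9, 3.9, length.out = n)
    scene <- build_contact_scene(n, distances = dists, decoys = 50, seed = seed)
    pairs <- find_contacts(scene$structure, "P", "R")
    expect_equal(nrow(pairs), n)
    expect_equal(nrow(pairs), brute_force_contacts(scene$structure, "P", "R", 4.0))
    led <- scene$ledger[order(scene$ledger$pep_serial), ]
    got <- pairs[order(pairs$pep_serial), ]
    expect_equal(got$rec_serial, led$rec_serial)
    expect_equal(got$distance, led$distance, tolerance = 1e-9)
    expect_equal(got$kind, led$kind)
  }
})

test_that("contact counts are monotone in the cutoff and split is nested", {
  scene <- build_contact_scene(6, distances = c(2.8, 3.2, 3.45, 3.6, 3.8, 3.95),
                               decoys = 40, seed = 9)
  n35 <- nrow(find_contacts(scene$structure, "P", "R", vdw_cutoff = 3.5))
  n40 <- nrow(find_contacts(scene$structure, "P", "R", vdw_cutoff = 4.0))
  expect_lte(n35, n40)
  pairs <- find_contacts(scene$structure, "P", "R")
  expect_true(all(pairs$distance[pairs$kind == "hbond"] <= 3.4))
  expect_true(all(pairs$distance <= 4.0))
})

test_that("grand totals are invariant to receptor-chain ordering", {
  cx <- build_toy_complex()
  # split receptor into two chains
  atoms <- tibble::as_tibble(cx)
  atoms$chain_id[atoms$chain_id == "R" & atoms$res_seq > 106] <- "S"
  s <- pfrkit:::new_pfr_structure(atoms)
  a <- find_contacts(s, "P", c("R", "S"))
  b <- find_contacts(s, "P", c("S", "R"))
  expect_equal(nrow(a), nrow(b))
  expect_equal(sort(a$distance), sort(b$distance))
})

test_that("cutoff validation and empty selections error", {
  s <- two_atom_structure(3.0)
  expect_error(find_contacts(s, "P", "R", vdw_cutoff = -1), "positive")
  expect_error(find_contacts(s, "Z", "R"), "empty")
  expect_error(find_contacts(s, "P", "Z"), "empty")
})

test_that("the contact table sums per residue, region and grand total", {
  cx <- build_toy_complex()
  reg <- assign_register(cx, "P", core_start = 2)
  pairs <- find_contacts(cx, "P", "R")
  tab <- summarize_contacts(pairs, reg)
  expect_equal(nrow(tab), 13)
  expect_true(all(tab$total == tab$vdw + tab$hbond))
  expect_true(all(tab$hbond <= tab$total))
  tot <- glance(tab)
  all_row <- tot[tot$region == "all", ]
  expect_equal(all_row$total, nrow(pairs))
  expect_equal(all_row$vdw, sum(pairs$kind == "vdw"))
  expect_equal(all_row$hbond, sum(pairs$kind == "hbond"))
  expect_equal(sum(tab$total), all_row$total)
  # region totals add up to member rows
  for (rg in c("N-PFR", "core", "C-PFR")) {
    expect_equal(tot$total[tot$region == rg], sum(tab$total[tab$region == rg]))
  }
  expect_equal(tot$total[tot$region == "PFR"],
               sum(tab$total[tab$region != "core"]))
  # percentages of contacting residues sum to 100
  expect_equal(sum(tab$pct), 100, tolerance = 1e-9)
  expect_true(all(diff(tab$p_pos) > 0))
})

test_that("an empty pair list gives an all-zero table", {
  cx <- build_toy_complex(offset = 50)
  reg <- assign_register(cx, "P", core_start = 2)
  pairs <- find_contacts(cx, "P", "R")
  expect_equal(nrow(pairs), 0)
  tab <- summarize_contacts(pairs, reg)
  expect_true(all(tab$total == 0))
  expect_true(all(tab$pct == 0))
  expect_equal(glance(tab)$total[glance(tab)$region == "all"], 0)
})

test_that("contacts outside the register are refused by name", {
  cx <- build_toy_complex()
  reg <- assign_register(cx, "P", core_start = 2)
  reg_cut <- reg[reg$res_seq > 1, ]
  attr(reg_cut, "core_start") <- 2L
  pairs <- find_contacts(cx, "P", "R")
  if (any(pairs$pep_res_seq == 1)) {
    expect_error(summarize_contacts(pairs, reg_cut), "PHE1")
  }
})

test_that("per-atom detail splits backbone from side chain", {
  cx <- build_toy_complex()
  reg <- assign_register(cx, "P", core_start = 2)
  pairs <- find_contacts(cx, "P", "R")
  det <- residue_contact_detail(pairs, reg, p_pos = 2)
  expect_true(all(det$atom_class[det$pep_name %in% c("N", "CA", "C", "O")] ==
                    "backbone"))
  expect_true(all(det$atom_class[det$pep_name == "CB"] == "side-chain"))
  expect_equal(nrow(det), sum(pairs$pep_res_seq ==
                                reg$res_seq[reg$p_pos == 2]))

  # a planted single pair comes back as exactly that listing
  scene <- build_contact_scene(1, distances = 3.0, decoys = 10, seed = 2)
  sreg <- tibble::tibble(chain_id = "P", res_seq = 1L, icode = "",
                         res_name = "SER", aa = "S", pep_index = 1L,
                         p_pos = 1L, region = "core", anchor = TRUE)
  spairs <- find_contacts(scene$structure, "P", "R")
  sdet <- residue_contact_detail(spairs, sreg, p_pos = 1)
  expect_equal(nrow(sdet), 1)
  expect_equal(sdet$pep_name, scene$ledger$pep_name)
  expect_equal(sdet$atom_class, "side-chain")
})

test_that("glycine contributes backbone-only contacts", {
  gly <- build_peptide("G", phi = 0, psi = 0, chain_id = "P")
  partner <- tibble::as_tibble(build_peptide("A", phi = 0, psi = 0, chain_id = "R"))
  partner$z <- partner$z + 3.5
  partner$serial <- partner$serial + 10L
  s <- pfrkit:::new_pfr_structure(rbind(tibble::as_tibble(gly), partner))
  pairs <- find_contacts(s, "P", "R")
  expect_true(nrow(pairs) > 0)
  expect_true(all(pairs$pep_name %in% c("N", "CA", "C", "O")))
})
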