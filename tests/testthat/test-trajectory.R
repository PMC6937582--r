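test_that("fitting removes pure rigid-body motion", {
  pep <- build_peptide("LAELA", phi = -120, psi = 130)
  base <- as.matrix(pep[, c("x", "y", "z")])
  coords <- array(NA_real_, c(nrow(pep), 3, 5))
  coords[, , 1] <- base
  for (f in 2:5) {
    coords[, , f] <- rigid_transform(base, angles = c(10, 20, 30) * f,
                                     shift = c(1, -2, 3) * f)
  }
  traj <- pfrkit:::new_pfr_trajectory(tibble::as_tibble(pep), coords)
  fitted <- fit_frames(traj, name == "CA")
  for (f in 2:5) {
    expect_lt(max(abs(fitted$coords[, , f] - fitted$coords[, , 1])), 1e-6)
  }
})

test_that("a single-frame trajectory is unchanged by fitting", {
  pep <- build_peptide("LAELA", phi = -120, psi = 130)
  traj <- make_jitter_traj(pep, 0, n_frames = 1, seed = 1)$trajectory
  fitted <- fit_frames(traj, name == "CA")
  expect_equal(fitted$coords, traj$coords, tolerance = 1e-9)
  expect_error(fit_frames(traj, chain_id == "Z"), "selects no atoms")
})

test_that("fitting absorbs little of the injected jitter", {
  pep <- build_peptide(strrep("A", 40), phi = -120, psi = 130)  # 200 atoms
  jt <- make_jitter_traj(pep, sigma = 0.5, n_frames = 400, seed = 21)
  fitted <- fit_frames(jt$trajectory, name == "CA")
  prof <- rmsf_profile(fitted)
  expected <- 0.5 * sqrt(3)
  expect_true(all(abs(prof$rmsf - expected) / expected < 0.10))
  # mean absorption across residues stays under 5%
  expect_lt(abs(mean(prof$rmsf) - expected) / expected, 0.05)
})

test_that("RMSF is zero on a constant trajectory and errors on one frame", {
  pep <- build_peptide("LAELA", phi = -120, psi = 130)
  const <- make_jitter_traj(pep, 0, n_frames = 10, seed = 1)$trajectory
  expect_true(all(rmsf_profile(const)$rmsf == 0))
  single <- make_jitter_traj(pep, 0, n_frames = 1, seed = 1)$trajectory
  expect_error(rmsf_profile(single), "at least 2")
})

test_that("isotropic jitter gives the closed-form RMSF of sigma*sqrt(3)", {
  pep <- build_peptide("LAELA", phi = -120, psi = 130)
  jt <- make_jitter_traj(pep, sigma = 1.0, n_frames = 5000, seed = 17)
  prof <- rmsf_profile(jt$trajectory)   # unfitted: noise is the only motion
  expect_equal(nrow(prof), 5)
  expect_true(all(abs(prof$rmsf - sqrt(3)) / sqrt(3) < 0.02))
})

test_that("a sigma ramp yields a flank-high RMSF profile", {
  pep <- build_peptide("AAAAAAAAA", phi = -120, psi = 130)
  sig <- c(2, 1.2, 0.6, 0.35, 0.3, 0.35, 0.6, 1.2, 2)
  jt <- make_jitter_traj(pep, sigma = sig, n_frames = 800, seed = 5)
  prof <- rmsf_profile(jt$trajectory)
  expect_gt(prof$rmsf[1], prof$rmsf[5])
  expect_gt(prof$rmsf[9], prof$rmsf[5])
  expect_equal(prof$rmsf, sig * sqrt(3), tolerance = 0.12)
})

test_that("RMSF is invariant to a global rigid transform before fitting", {
  pep <- build_peptide("LAELA", phi = -120, psi = 130)
  jt <- make_jitter_traj(pep, sigma = 0.7, n_frames = 200, seed = 8)
  tr <- jt$trajectory
  moved <- tr
  for (f in seq_len(n_frames(tr))) {
    moved$coords[, , f] <- rigid_transform(tr$coords[, , f])
  }
  r1 <- rmsf_profile(fit_frames(tr, name == "CA"))
  r2 <- rmsf_profile(fit_frames(moved, name == "CA"))
  expect_equal(r1$rmsf, r2$rmsf, tolerance = 1e-9)
})

test_that("contact fractions recover planted shares and sum to 100", {
  scene <- build_contact_scene(4, distances = c(2.8, 2.8, 2.8, 2.8),
                               decoys = 20, seed = 4)
  tr <- as_trajectory(scene$structure)
  tr$coords <- array(rep(tr$coords, 6), c(dim(tr$coords)[1], 3, 6))
  cf <- traj_contact_fraction(tr, "P", "R", cutoff = 3.0)
  expect_equal(nrow(cf), 4)
  expect_equal(cf$pct, rep(25, 4))
  expect_equal(sum(cf$pct), 100)

  # only one residue within reach: it takes 100%
  one <- build_contact_scene(1, distances = 2.5, decoys = 5, seed = 6)
  tro <- as_trajectory(one$structure)
  tro$coords <- array(rep(tro$coords, 3), c(dim(tro$coords)[1], 3, 3))
  cfo <- traj_contact_fraction(tro, "P", "R", cutoff = 3.0)
  expect_equal(cfo$pct, 100)
})

test_that("per-frame planted contact counts aggregate exactly", {
  # frame 1: both residues in contact; frames 2-3: residue 1 only
  s <- build_contact_scene(2, distances = c(2.0, 2.0), decoys = 0, seed = 1)$structure
  base <- as.matrix(s[, c("x", "y", "z")])
  coords <- array(rep(base, 3), c(nrow(s), 3, 3))
  rec2 <- which(s$chain_id == "R" & s$res_seq == 102)
  coords[rec2, 3, 2:3] <- coords[rec2, 3, 2:3] + 50   # move partner away
  tr <- pfrkit:::new_pfr_trajectory(tibble::as_tibble(s), coords)
  cf <- traj_contact_fraction(tr, "P", "R", cutoff = 3.0)
  # residue 1 contacts in 3 frames, residue 2 in 1 frame: shares 75/25
  expect_equal(cf$count, c(3, 1))
  expect_equal(cf$pct, c(75, 25))
})

test_that("dihedral occupancy recovers the switching probability", {
  sw <- make_switch_traj("LSGSL", p_a = 0.28, n_frames = 4000, seed = 31,
                         window = c(2, 3))
  occ <- dihedral_occupancy(sw$trajectory, "P", 2, 3)
  frac_a <- occ$fractions$fraction[occ$fractions$state == "type II β-turn"]
  # downstream classification equals the generator ledger exactly
  expect_identical(frac_a, mean(sw$ledger$state == "A"))
  expect_equal(frac_a, 0.28, tolerance = 0.05)
  # exclusive exhaustive states sum to one
  expect_equal(sum(occ$fractions$fraction), 1)
  expect_equal(occ$per_frame$state == "type II β-turn",
               sw$ledger$state == "A")
})

test_that("occupancy is exact at the extremes", {
  all_a <- make_switch_traj("LSGSL", p_a = 1, n_frames = 50, seed = 2,
                            window = c(2, 3))
  occ <- dihedral_occupancy(all_a$trajectory, "P", 2, 3)
  expect_equal(occ$fractions$fraction[occ$fractions$state == "type II β-turn"], 1)
  none <- make_switch_traj("LSGSL", p_a = 0, n_frames = 50, seed = 2,
                           window = c(2, 3))
  occ0 <- dihedral_occupancy(none$trajectory, "P", 2, 3)
  expect_equal(occ0$fractions$fraction[occ0$fractions$state == "type II β-turn"], 0)
})

test_that("marginal occupancy reports per-residue window membership", {
  sw <- make_switch_traj("LSGSL", p_a = 0.4, n_frames = 500, seed = 12,
                         window = c(2, 3))
  occ <- dihedral_occupancy(sw$trajectory, "P", 2, 3, joint = FALSE)
  # residue i+1 stays at the type II ideal in both states
  m_i1 <- occ$fractions$fraction[occ$fractions$state == "type II β-turn" &
                                   occ$fractions$residue == "i+1"]
  expect_equal(m_i1, 1)
  m_i2 <- occ$fractions$fraction[occ$fractions$state == "type II β-turn" &
                                   occ$fractions$residue == "i+2"]
  expect_identical(m_i2, mean(sw$ledger$state == "A"))
})

test_that("clustering finds the planted conformers and honours the threshold", {
  m <- list(build_peptide("LSGS", phi = -60, psi = 120),
            build_peptide("LSGS", phi = -180, psi = 180),
            build_peptide("LSGS", phi = -57, psi = -47))
  n_fr <- 24
  coords <- array(NA_real_, c(nrow(m[[1]]), 3, n_fr))
  truth <- integer(n_fr)
  for (f in seq_len(n_fr)) {
    k <- (f - 1) %% 3 + 1
    truth[f] <- k
    coords[, , f] <- as.matrix(m[[k]][, c("x", "y", "z")])
  }
  tr <- pfrkit:::new_pfr_trajectory(tibble::as_tibble(m[[1]]), coords)
  cl <- cluster_frames(tr, threshold = 2.5)
  expect_equal(glance(cl)$n_clusters, 3)
  # memberships match the construction (up to label permutation)
  expect_equal(length(unique(paste(cl$cluster, truth))), 3)
  s <- tidy(cl)
  expect_equal(sort(s$n_members), rep(8, 3))
  expect_true(all(s$medoid_frame %in% cl$frame))

  # all frames identical -> one cluster; huge threshold -> one cluster
  same <- pfrkit:::new_pfr_trajectory(tibble::as_tibble(m[[1]]),
                                      array(rep(coords[, , 1], 5),
                                            c(nrow(m[[1]]), 3, 5)))
  expect_equal(glance(cluster_frames(same))$n_clusters, 1)
  expect_equal(glance(cluster_frames(tr, threshold = 1000))$n_clusters, 1)
})

test_that("cluster count is non-increasing in the threshold", {
  pep <- build_peptide("LSGS", phi = -120, psi = 120)
  jt <- make_jitter_traj(pep, sigma = 1.5, n_frames = 40, seed = 13)
  counts <- vapply(c(0.5, 1, 2, 3.5, 5, 8), function(h) {
    glance(cluster_frames(jt$trajectory, threshold = h))$n_clusters
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("oversize trajectories demand a stride", {
  pep <- build_peptide("AA", phi = -120, psi = 120)
  big <- make_jitter_traj(pep, sigma = 0.1, n_frames = 5001, seed = 1)
  expect_error(cluster_frames(big$trajectory, threshold = 2.5), "stride")
  cl <- cluster_frames(big$trajectory, threshold = 2.5, stride = 100)
  expect_lte(nrow(cl), 51)
})
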