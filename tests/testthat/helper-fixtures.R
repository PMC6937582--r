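# Shared fixtures and independent oracles. The contact oracle is a plain
# nested double loop so it shares no code with the vectorised
# implementation it checks.

brute_force_contacts <- function(structure, peptide_chain, receptor_chains,
                                 cutoff = 4.0) {
  pep <- structure[structure$chain_id == peptide_chain &
                     !(structure$res_name %in% c("HOH", "WAT")), ]
  rec <- structure[structure$chain_id %in% receptor_chains &
                     !(structure$res_name %in% c("HOH", "WAT")), ]
  n <- 0L
  for (i in seq_len(nrow(pep))) {
    for (j in seq_len(nrow(rec))) {
      d <- sqrt((pep$x[i] - rec$x[j])^2 + (pep$y[i] - rec$y[j])^2 +
                  (pep$z[i] - rec$z[j])^2)
      if (d <= cutoff) n <- n + 1L
    }
  }
  n
}

# Apply a rigid rotation (Euler angles, degrees) + translation to an atom
# table or an n x 3 matrix.
rigid_transform <- function(obj, angles = c(20, -35, 50), shift = c(5, -3, 8)) {
  a <- angles * pi / 180
  rx <- matrix(c(1, 0, 0, 0, cos(a[1]), -sin(a[1]), 0, sin(a[1]), cos(a[1])),
               3, 3, byrow = TRUE)
  ry <- matrix(c(cos(a[2]), 0, sin(a[2]), 0, 1, 0, -sin(a[2]), 0, cos(a[2])),
               3, 3, byrow = TRUE)
  rz <- matrix(c(cos(a[3]), -sin(a[3]), 0, sin(a[3]), cos(a[3]), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  r <- rz %*% ry %*% rx
  if (is.matrix(obj)) {
    return(sweep(obj %*% t(r), 2, shift, "+"))
  }
  xyz <- sweep(as.matrix(obj[, c("x", "y", "z")]) %*% t(r), 2, shift, "+")
  obj$x <- xyz[, 1]; obj$y <- xyz[, 2]; obj$z <- xyz[, 3]
  obj
}

# A hand-written 3-atom PDB fixture with known field values.
write_three_atom_pdb <- function(path) {
  writeLines(c(
    "HEADER    TEST FIXTURE",
    "CRYST1   56.960  121.290   68.960  90.00  90.00  90.00 P 21 21 21",
    "REMARK   2 RESOLUTION.    1.95 ANGSTROMS.",
    "ATOM      1  N   LEU P   1      11.104  13.207   9.005  1.00 30.10           N",
    "ATOM      2  CA  LEU P   1      12.560  13.300   9.120  1.00 31.20           C",
    "ATOM      3  C   LEU P   1      13.120  14.510   9.850  1.00 32.30           C",
    "END"), path)
  path
}

# Assemble a multi-model atom table from a trajectory (for write/read tests).
traj_to_multimodel <- function(traj) {
  frames <- lapply(seq_len(n_frames(traj)), function(f) {
    d <- traj$topology
    d$model <- f
    d$x <- traj$coords[, 1, f]
    d$y <- traj$coords[, 2, f]
    d$z <- traj$coords[, 3, f]
    d
  })
  pfrkit:::new_pfr_structure(do.call(rbind, frames))
}

# Toy pMHC-like complex: a 13-residue peptide chain P over a receptor chain
# R (a rigid copy of the same backbone offset in z so the chains interlace
# within contact range).
build_toy_complex <- function(offset = 4.5) {
  pep <- build_peptide("FLAELAALNLSGS", phi = -120, psi = 130, chain_id = "P")
  rec <- build_peptide("FLAELAALNLSGS", phi = -120, psi = 130, chain_id = "R")
  rec$z <- rec$z + offset
  rec$serial <- rec$serial + max(pep$serial)
  rec$res_seq <- rec$res_seq + 100L
  pfrkit:::new_pfr_structure(rbind(tibble::as_tibble(pep), tibble::as_tibble(rec)))
}

# Backbone coordinates of chain P residues in order, for cross-checks.
segment_atoms_test <- function(structure, res = 1:4,
                               names = c("N", "CA", "C", "O")) {
  out <- NULL
  for (r in res) {
    for (nm in names) {
      row <- structure[structure$res_seq == r & structure$name == nm, ]
      out <- rbind(out, as.matrix(row[1, c("x", "y", "z")]))
    }
  }
  out
}

deposited_path <- function(file) {
  file.path(system.file("extdata", package = "pfrkit"), "deposited", file)
}
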