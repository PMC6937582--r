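# Synthetic fixtures with exact ground truth: an internal-coordinate
# backbone builder (ideal bond geometry, caller-specified dihedrals), toy
# contact scenes with planted pairs, and stochastic trajectories whose
# generating parameters are returned as ledgers for parameter-recovery
# tests. Everything is deterministic under a fixed seed.

AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# Ideal backbone geometry (Angstrom / degrees).
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
BOND_C_O <- 1.231
BOND_CA_CB <- 1.530
BOND_CB_OG <- 1.417
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.5
ANGLE_C_CA_CB <- 110.1
ANGLE_CA_CB_OG <- 110.8

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Build a peptide from backbone dihedrals
#'
#' Constructs a peptide chain atom-by-atom from internal coordinates:
#' ideal bond lengths and angles, trans peptide bonds unless overridden,
#' and the requested per-residue (phi, psi). Only the atoms the geometric
#' analyses touch are built: backbone N, CA, C, O, a CB stub on non-glycine
#' residues, and the side-chain hydroxyl of serine (OG) and threonine
#' (OG1). Re-measuring the built chain recovers the requested dihedrals to
#' well under half a degree.
#'
#' @param sequence One-letter amino-acid sequence (standard residues only).
#' @param phi,psi Per-residue dihedrals in degrees, recycled to the
#'   sequence length. `phi[1]` is unused (undefined at the N terminus);
#'   `psi` of the last residue only orients its carbonyl oxygen.
#' @param omega Peptide-bond torsion(s), degrees (default 180, trans).
#' @param chi1 Side-chain chi1 for Ser/Thr hydroxyl placement (default -65).
#' @param chain_id Chain identifier (default `"P"`).
#' @param b_iso B-factor written on every atom (default 20).
#' @return A single-model `pfr_structure` atom table.
#' @export
#' @examples
#' turn <- build_peptide("LSGS", phi = c(0, -60, 80, 0), psi = c(0, 120, 0, 0))
#' backbone_dihedrals(turn, "P")
build_peptide <- function(sequence, phi, psi, omega = 180, chi1 = -65,
                          chain_id = "P", b_iso = 20) {
  sequence <- toupper(gsub("\\s", "", sequence))
  n <- nchar(sequence)
  if (n == 0) stop("sequence is empty")
  aa <- strsplit(sequence, "")[[1]]
  bad <- !(aa %in% names(AA1TO3))
  if (any(bad)) stop("nonstandard residue(s): ", paste(unique(aa[bad]), collapse = ", "))
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  omega <- rep_len(omega, n)
  res3 <- unname(AA1TO3[aa])
  N <- CA <- C <- vector("list", n)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(BOND_N_CA, 0, 0)
  th <- deg2rad(180 - ANGLE_N_CA_C)
  C[[1]] <- CA[[1]] + BOND_CA_C * c(cos(th), sin(th), 0)
  for (i in seq_len(n)[-1]) {
    N[[i]] <- place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                         BOND_C_N, ANGLE_CA_C_N, psi[i - 1])
    CA[[i]] <- place_atom(CA[[i - 1]], C[[i - 1]], N[[i]],
                          BOND_N_CA, ANGLE_C_N_CA, omega[i])
    C[[i]] <- place_atom(C[[i - 1]], N[[i]], CA[[i]],
                         BOND_CA_C, ANGLE_N_CA_C, phi[i])
  }
  rows <- list()
  serial <- 0L
  push <- function(i, name, xyz) {
    serial <<- serial + 1L
    rows[[serial]] <<- tibble::tibble(
      model = 1L, serial = serial, name = name,
      element = substr(name, 1, 1), alt_loc = "", res_name = res3[i],
      chain_id = chain_id, res_seq = i, icode = "",
      x = xyz[1], y = xyz[2], z = xyz[3],
      occupancy = 1, b_iso = b_iso, het = FALSE)
  }
  for (i in seq_len(n)) {
    push(i, "N", N[[i]])
    push(i, "CA", CA[[i]])
    push(i, "C", C[[i]])
    push(i, "O", place_atom(N[[i]], CA[[i]], C[[i]],
                            BOND_C_O, ANGLE_CA_C_O, psi[i] + 180))
    if (aa[i] != "G") {
      cb <- place_atom(N[[i]], C[[i]], CA[[i]], BOND_CA_CB, ANGLE_C_CA_CB, 122.6)
      push(i, "CB", cb)
      if (aa[i] %in% c("S", "T")) {
        og <- place_atom(N[[i]], CA[[i]], cb, BOND_CB_OG, ANGLE_CA_CB_OG, chi1)
        push(i, if (aa[i] == "S") "OG" else "OG1", og)
      }
    }
  }
  new_pfr_structure(dplyr::bind_rows(rows))
}

#' Toy contact scene with planted pairs
#'
#' Lays out a "peptide" chain and a "receptor" chain such that exactly
#' `n_planted` atom pairs lie under the 4.0 Angstrom contact cutoff, at the
#' requested distances, while `decoys` additional receptor atoms all sit
#' farther than 4.5 Angstrom from every peptide atom. Plants alternate
#' between hydrogen-bond chemistry (peptide Ser OG against a receptor
#' backbone carbonyl O) and plain carbon pairs, so the expected class of
#' each pair is known from its chemistry and distance.
#'
#' @param n_planted Number of planted contact pairs.
#' @param distances Planted pair distances in Angstrom, recycled to
#'   `n_planted`; each must be positive and below 4.0.
#' @param decoys Number of far-field decoy receptor atoms (default 50).
#' @param seed RNG seed for decoy placement.
#' @return A list: `structure` (the scene's atom table; peptide chain
#'   `"P"`, receptor chain `"R"`) and `ledger`, a tibble naming every
#'   planted pair with its distance and intended class.
#' @export
build_contact_scene <- function(n_planted, distances = 3.5, decoys = 50, seed = 1) {
  if (n_planted < 0) stop("n_planted must be non-negative")
  if (any(distances <= 0)) stop("planted distances must be positive")
  if (any(distances >= 4.0)) {
    stop("planted distances must fall under the 4.0 Angstrom cutoff")
  }
  distances <- rep_len(distances, max(n_planted, 1))[seq_len(n_planted)]
  spacing <- 12
  rows <- list()
  ledger <- list()
  serial <- 0L
  add <- function(chain, res_seq, res_name, name, xyz, het = FALSE) {
    serial <<- serial + 1L
    rows[[serial]] <<- tibble::tibble(
      model = 1L, serial = serial, name = name,
      element = substr(name, 1, 1), alt_loc = "", res_name = res_name,
      chain_id = chain, res_seq = res_seq, icode = "",
      x = xyz[1], y = xyz[2], z = xyz[3], occupancy = 1, b_iso = 20, het = het)
    serial
  }
  if (n_planted == 0) {
    # inert peptide anchor so the scene still has both chains
    add("P", 1L, "ALA", "CB", c(0, 0, 0))
  }
  for (k in seq_len(n_planted)) {
    hb_chem <- k %% 2L == 1L
    x0 <- spacing * k
    pep_serial <- if (hb_chem) add("P", k, "SER", "OG", c(x0, 0, 0))
    else add("P", k, "ALA", "CB", c(x0, 0, 0))
    rec_serial <- if (hb_chem) add("R", 100L + k, "GLY", "O", c(x0, 0, distances[k]))
    else add("R", 100L + k, "ALA", "CB", c(x0, 0, distances[k]))
    ledger[[k]] <- tibble::tibble(
      pep_serial = pep_serial, pep_res_seq = k,
      pep_name = if (hb_chem) "OG" else "CB",
      rec_serial = rec_serial, rec_res_seq = 100L + k,
      rec_name = if (hb_chem) "O" else "CB",
      distance = distances[k],
      kind = if (hb_chem && distances[k] <= 3.4) "hbond" else "vdw")
  }
  if (decoys > 0) {
    with_local_seed(seed, {
      dx <- stats::runif(decoys, -50, spacing * max(n_planted, 1) + 50)
      dy <- stats::runif(decoys, 20, 40)
      dz <- stats::runif(decoys, -20, 20)
      for (j in seq_len(decoys)) {
        add("R", 500L + j, "ALA", "CB", c(dx[j], dy[j], dz[j]))
      }
    })
  }
  scene <- new_pfr_structure(dplyr::bind_rows(rows))
  led <- if (n_planted > 0) dplyr::bind_rows(ledger) else tibble::tibble(
    pep_serial = integer(), pep_res_seq = integer(), pep_name = character(),
    rec_serial = integer(), rec_res_seq = integer(), rec_name = character(),
    distance = double(), kind = character())
  list(structure = scene, ledger = led, seed = seed)
}

#' Trajectory of Gaussian positional jitter around a base model
#'
#' Each frame displaces every atom of the base model by independent
#' Gaussian noise, isotropic per coordinate, with a per-residue standard
#' deviation. The closed-form expectation for the downstream Calpha RMSF
#' of a residue with noise sigma is `sigma * sqrt(3)`.
#'
#' @param base Single-model atom table.
#' @param sigma Noise standard deviation in Angstrom, scalar or one value
#'   per residue of `base` (in residue order).
#' @param n_frames Number of frames (at least 1).
#' @param seed RNG seed.
#' @return A list: `trajectory` (`pfr_trajectory`), `ledger` (tibble of
#'   `res_seq`, `sigma`), `seed`.
#' @export
make_jitter_traj <- function(base, sigma, n_frames, seed = 1) {
  if (n_frames < 1) stop("n_frames must be at least 1")
  if (any(sigma < 0)) stop("sigma must be non-negative")
  top <- tibble::as_tibble(base[base$model == 1, , drop = FALSE])
  res <- dplyr::distinct(top, .data$chain_id, .data$res_seq, .data$icode)
  sigma <- rep_len(sigma, nrow(res))
  key <- paste(top$chain_id, top$res_seq, top$icode)
  atom_sigma <- sigma[match(key, paste(res$chain_id, res$res_seq, res$icode))]
  n_at <- nrow(top)
  base_xyz <- cbind(top$x, top$y, top$z)
  coords <- array(NA_real_, dim = c(n_at, 3, n_frames))
  with_local_seed(seed, {
    for (f in seq_len(n_frames)) {
      noise <- matrix(stats::rnorm(n_at * 3, sd = atom_sigma), ncol = 3)
      coords[, , f] <- base_xyz + noise
    }
  })
  list(trajectory = new_pfr_trajectory(top, coords),
       ledger = tibble::tibble(res_seq = res$res_seq, sigma = sigma),
       seed = seed)
}

#' Two-state dihedral-switching trajectory
#'
#' Builds a peptide whose central window flips between two dihedral states
#' with known probability: each frame is the chain rebuilt with the window
#' residues at state A ideals (with probability `p_a`) or state B ideals.
#' The per-frame state draw is returned as a ledger, so downstream window
#' occupancy can be compared against the exact realised fraction, not just
#' the nominal probability.
#'
#' @param sequence One-letter sequence for the builder.
#' @param phi,psi Base dihedrals outside the window, recycled.
#' @param window Length-2 integer: residue indices of i+1 and i+2.
#' @param state_a,state_b Lists with `phi1`, `psi1`, `phi2`, `psi2`
#'   (degrees) for the window residues; defaults are the type II beta-turn
#'   ideals and the glycine-extended ideals.
#' @param p_a Probability of state A per frame, in \[0, 1\].
#' @param n_frames Number of frames (at least 1).
#' @param seed RNG seed.
#' @param chain_id Chain identifier (default `"P"`).
#' @return A list: `trajectory`, `ledger` (tibble of `frame`, `state`),
#'   `p_a_realised` (exact fraction of A frames drawn), `seed`.
#' @export
make_switch_traj <- function(sequence, phi = -120, psi = 120,
                             window = c(2L, 3L),
                             state_a = list(phi1 = -60, psi1 = 120, phi2 = 80, psi2 = 0),
                             state_b = list(phi1 = -60, psi1 = 120, phi2 = -60, psi2 = 140),
                             p_a, n_frames, seed = 1, chain_id = "P") {
  if (n_frames < 1) stop("n_frames must be at least 1")
  if (p_a < 0 || p_a > 1) stop("p_a must lie in [0, 1]")
  n <- nchar(gsub("\\s", "", sequence))
  if (length(window) != 2 || any(window < 2) || any(window > n - 1)) {
    stop("window residues must be interior residues of the sequence")
  }
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  conform <- function(st) {
    p <- phi; q <- psi
    p[window[1]] <- st$phi1; q[window[1]] <- st$psi1
    p[window[2]] <- st$phi2; q[window[2]] <- st$psi2
    build_peptide(sequence, p, q, chain_id = chain_id)
  }
  mod_a <- conform(state_a)
  mod_b <- conform(state_b)
  xyz_a <- cbind(mod_a$x, mod_a$y, mod_a$z)
  xyz_b <- cbind(mod_b$x, mod_b$y, mod_b$z)
  draws <- with_local_seed(seed, stats::runif(n_frames) < p_a)
  coords <- array(NA_real_, dim = c(nrow(mod_a), 3, n_frames))
  for (f in seq_len(n_frames)) {
    coords[, , f] <- if (draws[f]) xyz_a else xyz_b
  }
  top <- tibble::as_tibble(mod_a)
  list(trajectory = new_pfr_trajectory(top, coords),
       ledger = tibble::tibble(frame = seq_len(n_frames),
                               state = ifelse(draws, "A", "B")),
       p_a_realised = mean(draws),
       seed = seed)
}
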