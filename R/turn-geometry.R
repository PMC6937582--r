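# Backbone dihedral analysis and reverse-turn classification. A four-residue
# window i..i+3 is labelled by the (phi, psi) angles of its two central
# residues against named ideal windows; membership is evaluated on the
# circle, so +180 and -180 coincide and "+/-140" targets are two centres.

resolve_residue_atoms <- function(structure, chain, model = 1L) {
  a <- structure[structure$model == model & structure$chain_id == chain &
                   !(structure$res_name %in% WATER_NAMES), , drop = FALSE]
  if (nrow(a) == 0) stop("chain '", chain, "' not found in model ", model)
  tibble::as_tibble(a)
}

# Named coordinate lookup: one residue's atom, first conformer wins.
atom_xyz <- function(atoms, res_seq, icode, name) {
  k <- which(atoms$res_seq == res_seq & atoms$icode == icode & atoms$name == name)
  if (!length(k)) return(NULL)
  c(atoms$x[k[1]], atoms$y[k[1]], atoms$z[k[1]])
}

#' Backbone dihedral angles of a chain
#'
#' Computes phi, psi and omega for every residue of a chain in the IUPAC
#' convention. Angles undefined at the termini (phi of the first residue,
#' psi and the following omega of the last) are `NA`, as are angles broken
#' by missing backbone atoms (reported with a warning). Omega for residue
#' i is the CA(i-1)-C(i-1)-N(i)-CA(i) torsion of the peptide bond
#' preceding it; it is reported but never used for turn classification.
#'
#' @param structure Atom table.
#' @param chain Chain identifier.
#' @param model Model number (default 1).
#' @return A tibble with `res_seq`, `icode`, `res_name`, `phi`, `psi`,
#'   `omega` in degrees in (-180, 180].
#' @export
backbone_dihedrals <- function(structure, chain, model = 1L) {
  atoms <- resolve_residue_atoms(structure, chain, model)
  res <- dplyr::distinct(atoms, .data$res_seq, .data$icode, .data$res_name)
  n <- nrow(res)
  if (n < 2) stop("chain '", chain, "' has fewer than 2 residues")
  get <- function(i, name) {
    if (i < 1 || i > n) return(NULL)
    atom_xyz(atoms, res$res_seq[i], res$icode[i], name)
  }
  phi <- psi <- omega <- rep(NA_real_, n)
  incomplete <- character()
  for (i in seq_len(n)) {
    Ni <- get(i, "N"); CAi <- get(i, "CA"); Ci <- get(i, "C")
    if (is.null(Ni) || is.null(CAi) || is.null(Ci)) {
      incomplete <- c(incomplete, paste0(res$res_name[i], res$res_seq[i]))
      next
    }
    Cm <- get(i - 1L, "C")
    if (!is.null(Cm)) phi[i] <- torsion_angle(Cm, Ni, CAi, Ci)
    Np <- get(i + 1L, "N")
    if (!is.null(Np)) psi[i] <- torsion_angle(Ni, CAi, Ci, Np)
    CAm <- get(i - 1L, "CA")
    if (!is.null(CAm) && !is.null(Cm)) omega[i] <- torsion_angle(CAm, Cm, Ni, CAi)
  }
  if (length(incomplete)) {
    warning("incomplete backbone at ", paste(incomplete, collapse = ", "),
            "; adjacent dihedrals are NA")
  }
  tibble::tibble(res_seq = res$res_seq, icode = res$icode,
                 res_name = res$res_name, phi = phi, psi = psi, omega = omega)
}

#' Define a named dihedral window for turn classification
#'
#' A window specifies ideal (phi, psi) targets for the two central residues
#' of a four-residue turn, each target possibly a set of centres (so a
#' "+/-140 degrees" ideal is the pair of centres +140 and -140), plus an
#' angular tolerance. Membership uses the minimal circular difference.
#'
#' @param name Label returned by [classify_window()] on a match.
#' @param phi1,psi1 Target centre(s), degrees, for residue i+1.
#' @param phi2,psi2 Target centre(s), degrees, for residue i+2.
#' @param tolerance Half-width of the window in degrees (default 40).
#' @return A `pfr_turn_spec` list.
#' @export
turn_window_spec <- function(name, phi1, psi1, phi2, psi2, tolerance = 40) {
  if (tolerance <= 0) stop("tolerance must be positive")
  structure(list(name = name, phi1 = phi1, psi1 = psi1,
                 phi2 = phi2, psi2 = psi2, tolerance = tolerance),
            class = "pfr_turn_spec")
}

#' Default turn windows
#'
#' Two windows cover the conformations relevant to a C-terminal flanking
#' hairpin: the ideal type II beta-turn, with central dihedrals
#' (phi, psi) = (-60, +120) at i+1 and (+80, 0) at i+2, and a
#' glycine-extended window in which i+2 relaxes to the mirror glycine
#' region (-60, +/-140) while i+1 stays turn-like.
#'
#' @param tolerance Half-width in degrees applied to both windows
#'   (default 40).
#' @return A list of [turn_window_spec()] objects, in match priority order.
#' @export
turn_specs <- function(tolerance = 40) {
  list(
    turn_window_spec("type II β-turn", -60, 120, 80, 0, tolerance),
    turn_window_spec("glycine-extended", -60, 120, -60, c(140, -140), tolerance))
}

in_window <- function(angle, centers, tolerance) {
  hit <- rep(FALSE, length(angle))
  for (ctr in centers) hit <- hit | (circular_diff(angle, ctr) <= tolerance)
  hit
}

#' Classify a four-residue window by its central dihedrals
#'
#' Tests the (phi, psi) pairs of residues i+1 and i+2 against each window
#' spec in order; the first spec whose four angle conditions all hold wins,
#' and windows matching none are `"other"`. Inputs are recycled vectors, so
#' a whole trajectory's windows classify in one call. Classification is
#' invariant to adding full turns (360 degrees) to any input.
#'
#' @param phi1,psi1 Dihedrals of residue i+1, degrees.
#' @param phi2,psi2 Dihedrals of residue i+2, degrees.
#' @param specs List of [turn_window_spec()]; default [turn_specs()].
#' @return Character vector of window names / `"other"`.
#' @export
classify_window <- function(phi1, psi1, phi2, psi2, specs = turn_specs()) {
  n <- max(length(phi1), length(psi1), length(phi2), length(psi2))
  phi1 <- rep_len(phi1, n); psi1 <- rep_len(psi1, n)
  phi2 <- rep_len(phi2, n); psi2 <- rep_len(psi2, n)
  if (anyNA(c(phi1, psi1, phi2, psi2))) {
    stop("undefined dihedral angle in classify_window(); ",
         "windows at chain termini or gaps cannot be classified")
  }
  state <- rep("other", n)
  for (spec in rev(specs)) {
    hit <- in_window(phi1, spec$phi1, spec$tolerance) &
      in_window(psi1, spec$psi1, spec$tolerance) &
      in_window(phi2, spec$phi2, spec$tolerance) &
      in_window(psi2, spec$psi2, spec$tolerance)
    state[hit] <- spec$name
  }
  state
}

#' Hairpin / ST-loop evidence for a four-residue window
#'
#' Collects the geometric evidence that residues i..i+3 form a tight
#' reverse turn: the CA(i)-CA(i+3) distance (within `ca_cutoff` for a
#' hairpin), the i backbone-carbonyl to (i+3) side-chain-hydroxyl hydrogen
#' bond that defines a serine/threonine-capped (ST) loop, the longer-range
#' polar interaction from the same carbonyl to the (i+3) backbone amide,
#' and the dihedral-window classification of the two central residues.
#'
#' @param structure Atom table.
#' @param chain Chain identifier.
#' @param i_res `res_seq` of residue i (the window runs over the next three
#'   modeled residues in chain order).
#' @param hbond_cutoff Hydroxyl H-bond cutoff, Angstrom (default 3.4).
#' @param polar_cutoff Amide polar-interaction cutoff, Angstrom (default 3.6).
#' @param ca_cutoff Hairpin CA(i)-CA(i+3) cutoff, Angstrom (default 7.0).
#' @param specs Turn windows for classification (default [turn_specs()]).
#' @param model Model number (default 1).
#' @return A `pfr_turn` list: window residue table, `state`,
#'   `ca_distance_i_i3`, `hydroxyl_hbond` (distance or `NA`),
#'   `amide_polar` (distance or `NA`), `st_loop`, `is_hairpin`, and the
#'   cutoffs used. [tidy()] flattens it to one row.
#' @export
hairpin_evidence <- function(structure, chain, i_res,
                             hbond_cutoff = 3.4, polar_cutoff = 3.6,
                             ca_cutoff = 7.0, specs = turn_specs(), model = 1L) {
  atoms <- resolve_residue_atoms(structure, chain, model)
  res <- dplyr::distinct(atoms, .data$res_seq, .data$icode, .data$res_name)
  start <- which(res$res_seq == i_res)[1]
  if (is.na(start) || start + 3 > nrow(res)) {
    stop("window ", i_res, "..i+3 is not fully modeled in chain '", chain, "'")
  }
  win <- res[start:(start + 3), ]
  dih <- backbone_dihedrals(structure, chain, model)
  dih_win <- dih[match(paste(win$res_seq, win$icode),
                       paste(dih$res_seq, dih$icode)), ]
  if (anyNA(dih_win$phi[2:3]) || anyNA(dih_win$psi[2:3])) {
    stop("central window residues lack defined phi/psi")
  }
  state <- classify_window(dih_win$phi[2], dih_win$psi[2],
                           dih_win$phi[3], dih_win$psi[3], specs)
  ca_i <- atom_xyz(atoms, win$res_seq[1], win$icode[1], "CA")
  ca_i3 <- atom_xyz(atoms, win$res_seq[4], win$icode[4], "CA")
  o_i <- atom_xyz(atoms, win$res_seq[1], win$icode[1], "O")
  n_i3 <- atom_xyz(atoms, win$res_seq[4], win$icode[4], "N")
  if (is.null(ca_i) || is.null(ca_i3) || is.null(o_i)) {
    stop("window ", i_res, "..i+3 is missing backbone atoms")
  }
  ca_dist <- vnorm(ca_i3 - ca_i)
  hydroxyl_name <- switch(win$res_name[4], SER = "OG", THR = "OG1", NA_character_)
  hydroxyl <- NA_real_
  if (!is.na(hydroxyl_name)) {
    og <- atom_xyz(atoms, win$res_seq[4], win$icode[4], hydroxyl_name)
    if (!is.null(og)) hydroxyl <- vnorm(og - o_i)
  }
  amide <- if (is.null(n_i3)) NA_real_ else vnorm(n_i3 - o_i)
  structure(list(
    window = win,
    state = state,
    ca_distance_i_i3 = ca_dist,
    hydroxyl_hbond = hydroxyl,
    amide_polar = if (!is.na(amide) && amide <= polar_cutoff) amide else NA_real_,
    amide_distance = amide,
    st_loop = !is.na(hydroxyl) && hydroxyl <= hbond_cutoff,
    is_hairpin = ca_dist <= ca_cutoff,
    cutoffs = c(hbond = hbond_cutoff, polar = polar_cutoff, ca = ca_cutoff)),
    class = "pfr_turn")
}

#' @export
print.pfr_turn <- function(x, ...) {
  cat("# turn window ", paste0(x$window$res_name, x$window$res_seq, collapse = "-"),
      "\n#   state: ", x$state,
      sprintf("\n#   CA(i)-CA(i+3): %.2f A (hairpin: %s)", x$ca_distance_i_i3,
              x$is_hairpin),
      sprintf("\n#   carbonyl->hydroxyl: %s (ST loop: %s)",
              if (is.na(x$hydroxyl_hbond)) "absent" else sprintf("%.2f A", x$hydroxyl_hbond),
              x$st_loop), "\n", sep = "")
  invisible(x)
}

#' @rdname hairpin_evidence
#' @param x A `pfr_turn` object.
#' @param ... Unused.
#' @export
tidy.pfr_turn <- function(x, ...) {
  tibble::tibble(
    res_i = x$window$res_seq[1], res_i3 = x$window$res_seq[4],
    residues = paste0(x$window$res_name, x$window$res_seq, collapse = "-"),
    state = x$state,
    ca_distance_i_i3 = x$ca_distance_i_i3,
    hydroxyl_hbond = x$hydroxyl_hbond,
    amide_distance = x$amide_distance,
    st_loop = x$st_loop, is_hairpin = x$is_hairpin)
}

segment_atoms <- function(structure, chain, res, atom_names, model = 1L) {
  atoms <- resolve_residue_atoms(structure, chain, model)
  atoms <- atoms[atoms$res_seq %in% res, , drop = FALSE]
  res_order <- dplyr::distinct(atoms, .data$res_seq, .data$icode)
  out <- list()
  for (r in seq_len(nrow(res_order))) {
    for (nm in atom_names) {
      xyz <- atom_xyz(atoms, res_order$res_seq[r], res_order$icode[r], nm)
      if (is.null(xyz)) {
        stop("atom '", nm, "' not found in residue ", res_order$res_seq[r],
             " of chain '", chain, "'")
      }
      out[[length(out) + 1]] <- tibble::tibble(
        res_seq = res_order$res_seq[r], name = nm,
        x = xyz[1], y = xyz[2], z = xyz[3])
    }
  }
  dplyr::bind_rows(out)
}

#' Superpose two matched loop segments
#'
#' Least-squares rigid superposition of a mobile segment onto a reference
#' segment, pairing atoms residue-by-residue in order through `atom_names`,
#' and reporting the post-fit RMSD over the paired atoms. Used to compare a
#' presented-peptide loop against the equivalent loop of the native
#' antigen.
#'
#' @param mobile,reference Atom tables.
#' @param mobile_chain,reference_chain Chain identifiers.
#' @param mobile_res,reference_res Vectors of `res_seq` defining each
#'   segment; must select the same number of residues.
#' @param atom_names Atom pairing within each residue (default backbone
#'   `N, CA, C, O`).
#' @param mobile_model,reference_model Model numbers (default 1).
#' @return A `pfr_superposition` list with `rotation`, `translation`,
#'   `rmsd` (Angstrom), `n` paired atoms, and the pairing table.
#'   [glance()] returns the fit summary as a one-row tibble.
#' @export
superpose_segments <- function(mobile, reference,
                               mobile_chain, mobile_res,
                               reference_chain, reference_res,
                               atom_names = c("N", "CA", "C", "O"),
                               mobile_model = 1L, reference_model = 1L) {
  ms <- segment_atoms(mobile, mobile_chain, mobile_res, atom_names, mobile_model)
  rs <- segment_atoms(reference, reference_chain, reference_res, atom_names,
                      reference_model)
  if (nrow(ms) != nrow(rs)) {
    stop("segments pair ", nrow(ms), " vs ", nrow(rs),
         " atoms; they must match residue-for-residue")
  }
  fit <- kabsch(cbind(ms$x, ms$y, ms$z), cbind(rs$x, rs$y, rs$z))
  pairing <- tibble::tibble(
    mobile_res = ms$res_seq, reference_res = rs$res_seq, name = ms$name)
  structure(list(rotation = fit$rotation, translation = fit$translation,
                 rmsd = fit$rmsd, n = fit$n, pairing = pairing,
                 atom_names = atom_names),
            class = "pfr_superposition")
}

#' @export
print.pfr_superposition <- function(x, ...) {
  cat(sprintf("# superposition: %d atoms (%s), rmsd = %.3f A\n",
              x$n, paste(x$atom_names, collapse = ","), x$rmsd))
  invisible(x)
}

#' @rdname superpose_segments
#' @param x A `pfr_superposition` object.
#' @param ... Unused.
#' @export
glance.pfr_superposition <- function(x, ...) {
  tibble::tibble(rmsd = x$rmsd, n_atoms = x$n,
                 pairing = paste(x$atom_names, collapse = ","))
}

#' @rdname superpose_segments
#' @export
tidy.pfr_superposition <- function(x, ...) {
  x$pairing
}
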