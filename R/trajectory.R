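# Frame-ensemble analysis. A trajectory is a topology (one atom table) plus
# an n_atoms x 3 x n_frames coordinate array; a multi-model PDB is the
# minimum on-disk dialect, and any richer format can adapt to the same
# contract. Statistics follow the usual simulation-analysis conventions:
# rigid-body fitting before RMSF, all-atom contact counting per frame,
# per-frame dihedral-window classification, and agglomerative clustering on
# the pairwise coordinate RMSD.

ELEMENT_MASSES <- c(H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974, SE = 78.971, FE = 55.845,
                    ZN = 65.38, MG = 24.305)

element_mass <- function(element) {
  m <- ELEMENT_MASSES[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

new_pfr_trajectory <- function(topology, coords, frame_interval = NA_real_,
                               fitted = FALSE, fit_selection = NA_character_) {
  stopifnot(dim(coords)[1] == nrow(topology), dim(coords)[2] == 3)
  structure(list(topology = topology, coords = coords,
                 frame_interval = frame_interval,
                 fitted = fitted, fit_selection = fit_selection),
            class = "pfr_trajectory")
}

#' Number of frames in a trajectory
#' @param traj A `pfr_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @export
print.pfr_trajectory <- function(x, ...) {
  cat("# pfr_trajectory: ", nrow(x$topology), " atoms x ", n_frames(x),
      " frames", if (isTRUE(x$fitted)) paste0(" (fitted on ", x$fit_selection, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Treat a multi-model atom table as a trajectory
#'
#' Reshapes the models of a parsed multi-model structure into an ordered
#' frame ensemble sharing the first model's topology. Every model must have
#' the same atom count and order.
#'
#' @param structure Multi-model atom table from [read_structure()].
#' @param frame_interval Optional time between frames (metadata only, any
#'   unit).
#' @return A `pfr_trajectory`.
#' @export
as_trajectory <- function(structure, frame_interval = NA_real_) {
  models <- sort(unique(structure$model))
  first <- tibble::as_tibble(structure[structure$model == models[1], , drop = FALSE])
  n_at <- nrow(first)
  if (n_at == 0) stop("cannot build a trajectory from an empty model")
  coords <- array(NA_real_, dim = c(n_at, 3, length(models)))
  for (k in seq_along(models)) {
    m <- structure[structure$model == models[k], , drop = FALSE]
    if (nrow(m) != n_at) {
      stop("model ", models[k], " has ", nrow(m), " atoms; topology has ", n_at)
    }
    coords[, , k] <- cbind(m$x, m$y, m$z)
  }
  first$model <- 1L
  new_pfr_trajectory(first, coords, frame_interval)
}

#' Read a multi-model PDB file as a trajectory
#'
#' @param path Path to a multi-model PDB file.
#' @param frame_interval Optional time between frames (metadata only).
#' @return A `pfr_trajectory`.
#' @export
read_trajectory <- function(path, frame_interval = NA_real_) {
  as_trajectory(read_structure(path, multi = TRUE), frame_interval)
}

# Evaluate a tidy selection expression over the topology -> atom indices.
eval_selection <- function(traj, select_quo, what = "selection") {
  if (rlang::quo_is_null(select_quo)) return(seq_len(nrow(traj$topology)))
  keep <- rlang::eval_tidy(select_quo, data = traj$topology)
  if (!is.logical(keep) || length(keep) != nrow(traj$topology)) {
    stop(what, " must evaluate to one logical per topology atom")
  }
  idx <- which(keep & !is.na(keep))
  if (length(idx) == 0) stop(what, " selects no atoms")
  idx
}

#' Rigid-body fit of every frame onto a reference
#'
#' Superposes each frame onto the first frame's coordinates of the fit
#' selection (mass-weighted least squares by default, as is standard before
#' fluctuation analysis) and applies the resulting transform to all atoms
#' of the frame.
#'
#' @param traj A `pfr_trajectory`.
#' @param select Unquoted logical expression over topology columns choosing
#'   the fit atoms, e.g. `chain_id %in% c("A", "B") & name == "CA"`.
#' @param mass_weighted Weight the fit by atomic mass (default `TRUE`).
#' @param reference_frame Frame providing the fixed reference coordinates
#'   (default 1).
#' @return A fitted `pfr_trajectory`.
#' @export
fit_frames <- function(traj, select = NULL, mass_weighted = TRUE,
                       reference_frame = 1L) {
  quo <- rlang::enquo(select)
  idx <- eval_selection(traj, quo, "fit selection")
  w <- if (mass_weighted) element_mass(traj$topology$element[idx]) else NULL
  ref <- traj$coords[idx, , reference_frame]
  out <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    fit <- kabsch(traj$coords[idx, , f], ref, weights = w)
    out[, , f] <- apply_transform(traj$coords[, , f], fit)
  }
  new_pfr_trajectory(traj$topology, out, traj$frame_interval,
                     fitted = TRUE, fit_selection = rlang::as_label(quo))
}

#' Per-atom RMSF profile
#'
#' Root-mean-square fluctuation of each selected atom about its
#' time-averaged position: `RMSF = sqrt(mean_t ||x(t) - <x>||^2)`. Fit the
#' trajectory first ([fit_frames()]) so that global rigid motion does not
#' inflate the fluctuations; the fluctuation itself is unweighted.
#'
#' @param traj A (fitted) `pfr_trajectory` with at least 2 frames.
#' @param select Unquoted selection expression (default: all Calpha atoms,
#'   `name == "CA"`).
#' @return A `pfr_rmsf` tibble: `chain_id`, `res_seq`, `icode`,
#'   `res_name`, `name`, `rmsf` (Angstrom).
#' @export
rmsf_profile <- function(traj, select = NULL) {
  if (n_frames(traj) < 2) stop("RMSF needs at least 2 frames")
  quo <- rlang::enquo(select)
  if (rlang::quo_is_null(quo)) quo <- rlang::quo(.data$name == "CA")
  idx <- eval_selection(traj, quo, "RMSF selection")
  xs <- traj$coords[idx, , , drop = FALSE]
  mean_pos <- apply(xs, c(1, 2), mean)
  dev2 <- sweep(xs, c(1, 2), mean_pos)^2
  rmsf <- sqrt(apply(dev2, 1, sum) / n_frames(traj))
  top <- traj$topology[idx, ]
  out <- tibble::tibble(chain_id = top$chain_id, res_seq = top$res_seq,
                        icode = top$icode, res_name = top$res_name,
                        name = top$name, rmsf = rmsf)
  structure(out, class = c("pfr_rmsf", class(out)),
            n_frames = n_frames(traj), fitted = traj$fitted,
            fit_selection = traj$fit_selection)
}

#' Per-residue share of peptide-receptor contacts over a trajectory
#'
#' Counts, frame by frame, every peptide-atom/receptor-atom pair within
#' `cutoff` (all atoms including hydrogens by default, matching the usual
#' simulation contact definition at short range) and reports each peptide
#' residue's percentage of the total contact count summed over all frames
#' and residues.
#'
#' @param traj A `pfr_trajectory`.
#' @param peptide_chain Peptide chain identifier.
#' @param receptor_chains Receptor chain identifiers.
#' @param cutoff Contact distance cutoff, Angstrom (default 3.0).
#' @param hydrogen_policy `"include"` (default) or `"exclude"`.
#' @return A `pfr_contact_fraction` tibble: `res_seq`, `icode`,
#'   `res_name`, `count` (summed over frames), `pct`.
#' @export
traj_contact_fraction <- function(traj, peptide_chain, receptor_chains,
                                  cutoff = 3.0,
                                  hydrogen_policy = c("include", "exclude")) {
  hydrogen_policy <- match.arg(hydrogen_policy)
  if (cutoff <= 0) stop("cutoff must be positive")
  top <- traj$topology
  keep_h <- if (hydrogen_policy == "include") rep(TRUE, nrow(top)) else
    !(top$element %in% c("H", "D"))
  pep_idx <- which(top$chain_id == peptide_chain &
                     !(top$res_name %in% WATER_NAMES) & keep_h)
  rec_idx <- which(top$chain_id %in% receptor_chains &
                     !(top$res_name %in% WATER_NAMES) & keep_h)
  if (!length(pep_idx)) stop("peptide selection '", peptide_chain, "' is empty")
  if (!length(rec_idx)) stop("receptor selection is empty")
  res_key <- paste(top$res_seq[pep_idx], top$icode[pep_idx])
  res_tab <- dplyr::distinct(top[pep_idx, ], .data$res_seq, .data$icode, .data$res_name)
  counts <- stats::setNames(rep(0, nrow(res_tab)),
                            paste(res_tab$res_seq, res_tab$icode))
  cut2 <- cutoff^2
  for (f in seq_len(n_frames(traj))) {
    frame <- traj$coords[, , f]
    d2 <- cross_dist2(frame[pep_idx, , drop = FALSE],
                      frame[rec_idx, , drop = FALSE])
    per_atom <- rowSums(d2 <= cut2)
    if (any(per_atom > 0)) {
      add <- tapply(per_atom, res_key, sum)
      counts[names(add)] <- counts[names(add)] + add
    }
  }
  grand <- sum(counts)
  out <- tibble::tibble(res_seq = res_tab$res_seq, icode = res_tab$icode,
                        res_name = res_tab$res_name,
                        count = as.numeric(counts[paste(res_tab$res_seq, res_tab$icode)]),
                        pct = if (grand > 0) 100 * as.numeric(counts[paste(res_tab$res_seq, res_tab$icode)]) / grand else 0)
  structure(out, class = c("pfr_contact_fraction", class(out)),
            cutoff = cutoff, hydrogen_policy = hydrogen_policy,
            n_frames = n_frames(traj), total_contacts = grand)
}

# Torsion across frames for four fixed atom indices; returns a vector.
frame_torsions <- function(traj, ia, ib, ic, id) {
  vapply(seq_len(n_frames(traj)), function(f) {
    torsion_angle(traj$coords[ia, , f], traj$coords[ib, , f],
                  traj$coords[ic, , f], traj$coords[id, , f])
  }, numeric(1))
}

topology_atom_index <- function(top, chain, res_seq, icode, name) {
  k <- which(top$chain_id == chain & top$res_seq == res_seq &
               top$icode == icode & top$name == name)
  if (!length(k)) {
    stop("atom '", name, "' of residue ", res_seq,
         " (chain '", chain, "') absent from topology")
  }
  k[1]
}

# Per-frame (phi, psi) of one residue identified by position in the chain's
# residue list.
residue_phi_psi_frames <- function(traj, chain, res_pos) {
  top <- traj$topology
  res <- dplyr::distinct(top[top$chain_id == chain &
                               !(top$res_name %in% WATER_NAMES), ],
                         .data$res_seq, .data$icode)
  i <- res_pos
  if (i < 2 || i >= nrow(res)) {
    stop("residue at chain position ", i,
         " lacks a neighbour; phi/psi undefined")
  }
  ix <- function(pos, name) topology_atom_index(top, chain, res$res_seq[pos],
                                                res$icode[pos], name)
  list(
    phi = frame_torsions(traj, ix(i - 1, "C"), ix(i, "N"), ix(i, "CA"), ix(i, "C")),
    psi = frame_torsions(traj, ix(i, "N"), ix(i, "CA"), ix(i, "C"), ix(i + 1, "N")))
}

#' Dihedral-window occupancy over a trajectory
#'
#' Classifies each frame's four-residue window (central residues i+1, i+2)
#' against the turn windows and reports the fraction of frames spent in
#' each state. With `joint = TRUE` (default) a frame is in a state only
#' when both central residues satisfy it simultaneously, via
#' [classify_window()]; the resulting states are exclusive and exhaustive,
#' so the fractions sum to 1. With `joint = FALSE` the per-residue marginal
#' window memberships are reported instead.
#'
#' @param traj A `pfr_trajectory`.
#' @param chain Chain identifier.
#' @param res_i1,res_i2 `res_seq` of residues i+1 and i+2.
#' @param specs Turn windows (default [turn_specs()]).
#' @param joint Joint (both-residue) or marginal classification.
#' @return A `pfr_occupancy` object: `fractions` tibble (`state`,
#'   `fraction`), `per_frame` tibble (`frame`, `state`) for the joint mode,
#'   counts and parameters. [tidy()] returns the fractions.
#' @export
dihedral_occupancy <- function(traj, chain, res_i1, res_i2,
                               specs = turn_specs(), joint = TRUE) {
  top <- traj$topology
  res <- dplyr::distinct(top[top$chain_id == chain &
                               !(top$res_name %in% WATER_NAMES), ],
                         .data$res_seq, .data$icode)
  pos1 <- which(res$res_seq == res_i1)[1]
  pos2 <- which(res$res_seq == res_i2)[1]
  if (is.na(pos1) || is.na(pos2)) {
    stop("window residues ", res_i1, "/", res_i2, " not found in chain '", chain, "'")
  }
  a1 <- residue_phi_psi_frames(traj, chain, pos1)
  a2 <- residue_phi_psi_frames(traj, chain, pos2)
  bad <- which(is.na(a1$phi) | is.na(a1$psi) | is.na(a2$phi) | is.na(a2$psi))
  if (length(bad)) {
    stop("undefined dihedrals in frame(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  nf <- n_frames(traj)
  if (joint) {
    state <- classify_window(a1$phi, a1$psi, a2$phi, a2$psi, specs)
    levels <- c(vapply(specs, `[[`, "", "name"), "other")
    frac <- vapply(levels, function(s) mean(state == s), numeric(1))
    fractions <- tibble::tibble(state = levels, fraction = unname(frac))
    per_frame <- tibble::tibble(frame = seq_len(nf), state = state)
  } else {
    rows <- list()
    for (spec in specs) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        state = spec$name, residue = "i+1",
        fraction = mean(in_window(a1$phi, spec$phi1, spec$tolerance) &
                          in_window(a1$psi, spec$psi1, spec$tolerance)))
      rows[[length(rows) + 1]] <- tibble::tibble(
        state = spec$name, residue = "i+2",
        fraction = mean(in_window(a2$phi, spec$phi2, spec$tolerance) &
                          in_window(a2$psi, spec$psi2, spec$tolerance)))
    }
    fractions <- dplyr::bind_rows(rows)
    per_frame <- NULL
  }
  structure(list(fractions = fractions, per_frame = per_frame,
                 joint = joint, n_frames = nf,
                 residues = c(res_i1, res_i2),
                 angles = list(i1 = a1, i2 = a2)),
            class = "pfr_occupancy")
}

#' @export
print.pfr_occupancy <- function(x, ...) {
  cat("# dihedral-window occupancy over ", x$n_frames, " frames (",
      if (x$joint) "joint" else "marginal", ")\n", sep = "")
  print(x$fractions)
  invisible(x)
}

#' @rdname dihedral_occupancy
#' @param x A `pfr_occupancy` object.
#' @param ... Unused.
#' @export
tidy.pfr_occupancy <- function(x, ...) x$fractions

#' Hierarchical agglomerative clustering of trajectory frames
#'
#' Builds the pairwise coordinate RMSD matrix over the selected atoms
#' (fit the trajectory first; no per-pair refitting is done), agglomerates
#' with the chosen linkage, and stops merging when the minimum
#' inter-cluster distance exceeds `threshold`. Clusters are numbered by
#' decreasing population and each is represented by its medoid, the member
#' frame minimising the summed RMSD to the rest of its cluster.
#'
#' @param traj A (fitted) `pfr_trajectory`.
#' @param select Unquoted atom selection expression (default all atoms).
#' @param threshold Minimum inter-cluster distance at which agglomeration
#'   stops, Angstrom (default 2.5).
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @param stride Analyse every `stride`-th frame. Required when the
#'   trajectory exceeds 5000 frames, to guard the quadratic RMSD matrix.
#' @return A `pfr_clusters` tibble (`frame`, `cluster`); the per-cluster
#'   summary (`cluster`, `n_members`, `medoid_frame`) is available via
#'   [tidy()] and the run summary via [glance()].
#' @export
cluster_frames <- function(traj, select = NULL, threshold = 2.5,
                           linkage = c("average", "complete", "single"),
                           stride = NULL) {
  linkage <- match.arg(linkage)
  if (threshold <= 0) stop("threshold must be positive")
  idx <- eval_selection(traj, rlang::enquo(select), "cluster selection")
  frames <- seq_len(n_frames(traj))
  if (!is.null(stride)) frames <- frames[seq(1, length(frames), by = stride)]
  if (length(frames) > 5000) {
    stop(length(frames), " frames exceed the exact pairwise-RMSD limit ",
         "(5000); pass a stride")
  }
  nf <- length(frames)
  flat <- t(vapply(frames, function(f) as.numeric(traj$coords[idx, , f]),
                   numeric(3 * length(idx))))
  if (nf == 1) {
    assign <- tibble::tibble(frame = frames, cluster = 1L)
    summary <- tibble::tibble(cluster = 1L, n_members = 1L, medoid_frame = frames)
  } else {
    d <- stats::dist(flat) / sqrt(length(idx))
    hc <- stats::hclust(d, method = linkage)
    raw <- stats::cutree(hc, h = threshold)
    sizes <- sort(table(raw), decreasing = TRUE)
    relabel <- stats::setNames(seq_along(sizes), names(sizes))
    cl <- as.integer(relabel[as.character(raw)])
    dm <- as.matrix(d)
    summary <- purrr::map_dfr(seq_along(sizes), function(k) {
      members <- which(cl == k)
      med <- members[which.min(rowSums(dm[members, members, drop = FALSE]))]
      tibble::tibble(cluster = k, n_members = length(members),
                     medoid_frame = frames[med])
    })
    assign <- tibble::tibble(frame = frames, cluster = cl)
  }
  structure(assign, class = c("pfr_clusters", class(assign)),
            summary = summary, threshold = threshold, linkage = linkage,
            n_selected_atoms = length(idx))
}

#' @rdname cluster_frames
#' @param x A `pfr_clusters` object.
#' @param ... Unused.
#' @export
tidy.pfr_clusters <- function(x, ...) attr(x, "summary", exact = TRUE)

#' @rdname cluster_frames
#' @export
glance.pfr_clusters <- function(x, ...) {
  s <- attr(x, "summary", exact = TRUE)
  tibble::tibble(n_clusters = nrow(s), n_frames = nrow(x),
                 threshold = attr(x, "threshold", exact = TRUE),
                 linkage = attr(x, "linkage", exact = TRUE))
}
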