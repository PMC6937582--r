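# Peptide-to-receptor contact enumeration. A contact is any heavy-atom (or
# all-atom, when hydrogens are included) pair within the vdW cutoff; pairs
# whose atoms form a donor/acceptor couple within the H-bond cutoff are
# classified as hydrogen bonds, everything else as van der Waals. A pair is
# never counted in both classes.

HBOND_DONORS <- list(
  "*"   = "N",                       # backbone amide of every residue
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"),
  TRP = "NE1", ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1", TYR = "OH")

HBOND_ACCEPTORS <- list(
  "*"   = c("O", "OXT"),             # backbone carbonyl / terminal carboxylate
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH", MET = "SD")

match_chem <- function(res_name, name, table) {
  hit <- name %in% table[["*"]]
  for (res in setdiff(names(table), "*")) {
    hit <- hit | (res_name == res & name %in% table[[res]])
  }
  hit
}

is_hbond_donor <- function(res_name, name) match_chem(res_name, name, HBOND_DONORS)
is_hbond_acceptor <- function(res_name, name) match_chem(res_name, name, HBOND_ACCEPTORS)

select_contact_atoms <- function(structure, chains, model, hydrogen_policy) {
  a <- structure[structure$model == model &
                   structure$chain_id %in% chains &
                   !(structure$res_name %in% WATER_NAMES), , drop = FALSE]
  if (hydrogen_policy == "exclude") {
    a <- a[!(a$element %in% c("H", "D")), , drop = FALSE]
  }
  tibble::as_tibble(a)
}

# Core pairing between two atom tables; returns one row per qualifying pair.
pair_atoms <- function(pep, rec, vdw_cutoff, hbond_cutoff) {
  d2 <- cross_dist2(cbind(pep$x, pep$y, pep$z), cbind(rec$x, rec$y, rec$z))
  hit <- which(d2 <= vdw_cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    out <- tibble::tibble(
      pep_serial = integer(), pep_name = character(), pep_element = character(),
      pep_res_name = character(), pep_res_seq = integer(), pep_icode = character(),
      rec_chain = character(), rec_serial = integer(), rec_name = character(),
      rec_element = character(), rec_res_name = character(), rec_res_seq = integer(),
      rec_icode = character(), distance = double(), kind = character())
    return(out)
  }
  i <- hit[, 1]; j <- hit[, 2]
  dist <- sqrt(pmax(d2[hit], 0))
  donor_pep <- is_hbond_donor(pep$res_name[i], pep$name[i]) &
    is_hbond_acceptor(rec$res_name[j], rec$name[j])
  donor_rec <- is_hbond_donor(rec$res_name[j], rec$name[j]) &
    is_hbond_acceptor(pep$res_name[i], pep$name[i])
  hbond <- (donor_pep | donor_rec) & dist <= hbond_cutoff
  out <- tibble::tibble(
    pep_serial = pep$serial[i], pep_name = pep$name[i], pep_element = pep$element[i],
    pep_res_name = pep$res_name[i], pep_res_seq = pep$res_seq[i], pep_icode = pep$icode[i],
    rec_chain = rec$chain_id[j], rec_serial = rec$serial[j], rec_name = rec$name[j],
    rec_element = rec$element[j], rec_res_name = rec$res_name[j],
    rec_res_seq = rec$res_seq[j], rec_icode = rec$icode[j],
    distance = dist,
    kind = ifelse(hbond, "hbond", "vdw"))
  dplyr::arrange(out, .data$pep_res_seq, .data$pep_serial, .data$distance)
}

#' Enumerate peptide-to-receptor atomic contacts
#'
#' Finds every peptide-atom/receptor-atom pair within `vdw_cutoff` and
#' partitions the pairs into hydrogen bonds (donor/acceptor chemistry within
#' `hbond_cutoff`) and van der Waals contacts (everything else). The H-bond
#' criterion is distance-only between donor and acceptor heavy atoms by
#' default; `min_donor_angle` adds an optional geometric filter on the
#' donor-antecedent/donor/acceptor angle. Waters are always excluded.
#'
#' @param structure Atom table.
#' @param peptide_chain Peptide chain identifier.
#' @param receptor_chains Character vector of receptor chain identifiers.
#' @param vdw_cutoff Van der Waals distance cutoff in Angstrom (default 4.0).
#' @param hbond_cutoff Hydrogen-bond distance cutoff in Angstrom (default 3.4).
#' @param hydrogen_policy `"exclude"` (default; appropriate for crystal
#'   models, which carry no informative hydrogens) or `"include"` (for
#'   simulation frames with modeled hydrogens).
#' @param min_donor_angle Optional minimum donor angle in degrees; `NULL`
#'   (default) disables the angle term.
#' @param model Model number (default 1).
#' @return A `pfr_contacts` tibble, one row per contact pair, with peptide
#'   atom fields (`pep_*`), receptor atom fields (`rec_*`), `distance`
#'   (Angstrom) and `kind` (`"vdw"` or `"hbond"`). Parameters are stored as
#'   attributes.
#' @export
find_contacts <- function(structure, peptide_chain, receptor_chains,
                          vdw_cutoff = 4.0, hbond_cutoff = 3.4,
                          hydrogen_policy = c("exclude", "include"),
                          min_donor_angle = NULL, model = 1L) {
  hydrogen_policy <- match.arg(hydrogen_policy)
  if (vdw_cutoff <= 0 || hbond_cutoff <= 0) stop("cutoffs must be positive")
  pep <- select_contact_atoms(structure, peptide_chain, model, hydrogen_policy)
  rec <- select_contact_atoms(structure, receptor_chains, model, hydrogen_policy)
  if (nrow(pep) == 0) stop("peptide selection '", peptide_chain, "' is empty")
  if (nrow(rec) == 0) {
    stop("receptor selection '", paste(receptor_chains, collapse = ","), "' is empty")
  }
  pairs <- pair_atoms(pep, rec, vdw_cutoff, hbond_cutoff)
  if (!is.null(min_donor_angle) && nrow(pairs) > 0) {
    pairs <- filter_donor_angle(pairs, pep, rec, min_donor_angle)
  }
  structure(pairs, class = c("pfr_contacts", class(pairs)),
            peptide_chain = peptide_chain, receptor_chains = receptor_chains,
            vdw_cutoff = vdw_cutoff, hbond_cutoff = hbond_cutoff,
            hydrogen_policy = hydrogen_policy, model = model)
}

# Demote hbond pairs whose donor angle (bonded heavy neighbour - donor -
# acceptor) is below the threshold back to vdw. The bonded neighbour is the
# nearest heavy atom of the donor's own residue within 1.8 Angstrom.
filter_donor_angle <- function(pairs, pep, rec, min_donor_angle) {
  coord <- function(df, serial) {
    k <- match(serial, df$serial)
    cbind(df$x[k], df$y[k], df$z[k])
  }
  hb <- which(pairs$kind == "hbond")
  for (k in hb) {
    pep_is_donor <- is_hbond_donor(pairs$pep_res_name[k], pairs$pep_name[k])
    donor_df <- if (pep_is_donor) pep else rec
    donor_serial <- if (pep_is_donor) pairs$pep_serial[k] else pairs$rec_serial[k]
    acc <- if (pep_is_donor) coord(rec, pairs$rec_serial[k]) else coord(pep, pairs$pep_serial[k])
    don <- coord(donor_df, donor_serial)
    same_res <- donor_df[donor_df$res_seq == donor_df$res_seq[match(donor_serial, donor_df$serial)] &
                           donor_df$chain_id == donor_df$chain_id[match(donor_serial, donor_df$serial)] &
                           donor_df$serial != donor_serial &
                           !(donor_df$element %in% c("H", "D")), , drop = FALSE]
    if (nrow(same_res) == 0) next
    dd <- sqrt(rowSums(sweep(cbind(same_res$x, same_res$y, same_res$z), 2, as.numeric(don))^2))
    nb <- which.min(dd)
    if (dd[nb] > 1.8) next
    ang <- bond_angle(c(same_res$x[nb], same_res$y[nb], same_res$z[nb]),
                      as.numeric(don), as.numeric(acc))
    if (ang < min_donor_angle) pairs$kind[k] <- "vdw"
  }
  pairs
}

#' Summarise contacts per registered residue and per region
#'
#' Tabulates van der Waals and hydrogen-bond contact counts for every
#' residue of the register (zero-contact residues included), together with
#' each residue's percentage share of the grand total, and computes the
#' N-PFR / core / C-PFR regional subtotals.
#'
#' @param pairs A [find_contacts()] result whose peptide atoms all belong
#'   to registered residues.
#' @param register A [assign_register()] result for the same peptide chain.
#' @return A `pfr_contact_table` tibble ordered by P-position with columns
#'   `p_pos`, `res_name`, `aa`, `region`, `vdw`, `hbond`, `total`, `pct`.
#'   The regional and grand totals are stored in the `region_totals`
#'   attribute and surfaced by [glance()].
#' @export
summarize_contacts <- function(pairs, register) {
  key <- paste(register$res_seq, register$icode)
  pk <- paste(pairs$pep_res_seq, pairs$pep_icode)
  orphan <- !(pk %in% key)
  if (any(orphan)) {
    stop("contact atoms outside the register at residue(s): ",
         paste(unique(paste0(pairs$pep_res_name[orphan], pairs$pep_res_seq[orphan])),
               collapse = ", "))
  }
  counts <- dplyr::count(tibble::as_tibble(pairs),
                         .data$pep_res_seq, .data$pep_icode, .data$kind)
  counts <- tidyr::pivot_wider(counts, names_from = "kind", values_from = "n",
                               values_fill = 0L)
  for (col in c("vdw", "hbond")) if (!col %in% names(counts)) counts[[col]] <- 0L
  tab <- dplyr::left_join(
    tibble::as_tibble(register)[, c("res_seq", "icode", "res_name", "aa", "p_pos", "region")],
    counts, by = c(res_seq = "pep_res_seq", icode = "pep_icode"))
  tab$vdw[is.na(tab$vdw)] <- 0L
  tab$hbond[is.na(tab$hbond)] <- 0L
  tab$total <- tab$vdw + tab$hbond
  grand <- sum(tab$total)
  tab$pct <- if (grand > 0) 100 * tab$total / grand else 0
  tab <- dplyr::arrange(tab, .data$p_pos)
  regions <- dplyr::summarise(
    dplyr::group_by(tab, .data$region),
    vdw = sum(.data$vdw), hbond = sum(.data$hbond), total = sum(.data$total),
    .groups = "drop")
  pfr <- dplyr::filter(regions, .data$region != "core")
  totals <- dplyr::bind_rows(
    regions,
    tibble::tibble(region = "PFR", vdw = sum(pfr$vdw), hbond = sum(pfr$hbond),
                   total = sum(pfr$total)),
    tibble::tibble(region = "all", vdw = sum(tab$vdw), hbond = sum(tab$hbond),
                   total = grand))
  structure(tab, class = c("pfr_contact_table", class(tab)),
            region_totals = totals,
            parameters = attributes(pairs)[c("vdw_cutoff", "hbond_cutoff",
                                             "hydrogen_policy")])
}

#' @export
print.pfr_contact_table <- function(x, ...) {
  NextMethod()
  tot <- attr(x, "region_totals", exact = TRUE)
  all <- tot[tot$region == "all", ]
  cat(sprintf("# totals: %d vdW + %d H-bond = %d contacts\n",
              all$vdw, all$hbond, all$total))
  invisible(x)
}

#' Region and grand contact totals
#'
#' @param x A `pfr_contact_table`.
#' @param ... Unused.
#' @return A tibble of regional subtotals (`N-PFR`, `core`, `C-PFR`, the
#'   combined `PFR` row, and `all`).
#' @export
glance.pfr_contact_table <- function(x, ...) {
  attr(x, "region_totals", exact = TRUE)
}

#' Per-atom contact listing for one registered residue
#'
#' Splits one residue's contacts into backbone (N, CA, C, O, OXT) and
#' side-chain atoms and lists every partner receptor atom with its
#' distance. Useful for dissecting how a single flanking residue, such as
#' an arginine upstream of P1, grips the receptor surface.
#'
#' @param pairs A [find_contacts()] result.
#' @param register The matching [assign_register()] result.
#' @param p_pos P-position of the residue of interest.
#' @return A tibble with one row per contact pair of that residue:
#'   `pep_name`, `atom_class`, `rec_chain`, `rec_res_name`, `rec_res_seq`,
#'   `rec_name`, `distance`, `kind`.
#' @export
residue_contact_detail <- function(pairs, register, p_pos) {
  row <- register[register$p_pos == p_pos, , drop = FALSE]
  if (nrow(row) == 0) stop("no registered residue at P", p_pos)
  sel <- pairs$pep_res_seq == row$res_seq[1] & pairs$pep_icode == row$icode[1]
  out <- tibble::as_tibble(pairs)[sel, , drop = FALSE]
  out$atom_class <- ifelse(out$pep_name %in% BACKBONE_NAMES, "backbone", "side-chain")
  out <- out[, c("pep_name", "atom_class", "rec_chain", "rec_res_name",
                 "rec_res_seq", "rec_name", "distance", "kind")]
  dplyr::arrange(out, .data$atom_class, .data$pep_name, .data$distance)
}
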