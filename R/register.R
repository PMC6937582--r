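# Register assignment: map the modeled peptide chain onto P-position
# numbering given the core nonamer start, and partition it into N-terminal
# flanking residues, the P1-P9 core, and C-terminal flanking residues.
# P-positions skip zero: ..., P(-2), P(-1), P1, ..., P9, P10, ...

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
            MSE = "M", SEC = "U", PYL = "O")

#' Anchor pocket positions of the class II core
#'
#' The nonamer core seats side chains in the P1, P4, P6 and P9 pockets of
#' the open-ended binding groove.
#' @return Integer vector `c(1, 4, 6, 9)`.
#' @export
anchor_positions <- function() c(1L, 4L, 6L, 9L)

p_position <- function(pep_index, core_start) {
  off <- pep_index - core_start            # 0 at P1
  ifelse(off >= 0, off + 1L, off)          # skip zero going N-terminal
}

#' Assign P-position register to a bound peptide
#'
#' Numbers the modeled residues of a peptide chain relative to the core
#' nonamer: residues before the core are N-terminal peptide-flanking
#' residues P(-1), P(-2), ... counting outwards, the core spans P1-P9, and
#' residues after it are C-terminal flanking residues P10, P11, ...
#'
#' @param structure Atom table from [read_structure()] or a builder.
#' @param peptide_chain Chain identifier of the peptide.
#' @param core_start 1-based index, along the modeled peptide chain, of the
#'   residue occupying pocket P1.
#' @param model Model number (default 1).
#' @return A `pfr_register` tibble with one row per modeled residue:
#'   `chain_id`, `res_seq`, `icode`, `res_name`, `aa` (one-letter code),
#'   `pep_index`, `p_pos`, `region` (`"N-PFR"`, `"core"`, `"C-PFR"`) and
#'   `anchor`. Attributes carry `core_start` and the anchor set.
#' @export
#' @examples
#' pep <- build_peptide("FARRPPLAELAALNLSGSRL", phi = -120, psi = 120)
#' assign_register(pep, "P", core_start = 7)
assign_register <- function(structure, peptide_chain, core_start, model = 1L) {
  a <- structure[structure$model == model &
                   structure$chain_id == peptide_chain &
                   !(structure$res_name %in% WATER_NAMES), , drop = FALSE]
  if (nrow(a) == 0) stop("peptide chain '", peptide_chain, "' not found")
  res <- dplyr::distinct(tibble::as_tibble(a),
                         .data$chain_id, .data$res_seq, .data$icode, .data$res_name)
  n <- nrow(res)
  core_start <- as.integer(core_start)
  if (core_start < 1 || core_start > n) {
    stop("core_start must index a modeled peptide residue (1..", n, ")")
  }
  if (n - core_start + 1 < 9) {
    stop("core_start = ", core_start, " leaves only ", n - core_start + 1,
         " residues; the core needs 9")
  }
  res$aa <- unname(AA3TO1[res$res_name])
  res$aa[is.na(res$aa)] <- "X"
  res$pep_index <- seq_len(n)
  res$p_pos <- p_position(res$pep_index, core_start)
  res$region <- dplyr::case_when(
    res$p_pos < 0 ~ "N-PFR",
    res$p_pos <= 9 ~ "core",
    TRUE ~ "C-PFR")
  res$anchor <- res$p_pos %in% anchor_positions()
  structure(res, class = c("pfr_register", class(res)),
            core_start = core_start, anchors = anchor_positions())
}

#' @export
print.pfr_register <- function(x, ...) {
  cat("# pfr_register: ", paste(x$aa, collapse = ""),
      " (core ", sum(x$region == "core"), ", N-PFR ", sum(x$region == "N-PFR"),
      ", C-PFR ", sum(x$region == "C-PFR"), ")\n", sep = "")
  NextMethod()
}

#' Report declared-but-unmodeled flanking residues
#'
#' Compares the modeled peptide sequence against the declared (synthesised
#' or genomic) sequence and reports residues present in the declaration but
#' absent from the coordinates, with the P-positions they would occupy.
#' Flanking residues frequently lack interpretable electron density, so
#' gaps at the termini are expected and must be surfaced rather than
#' silently dropped.
#'
#' @param register A [assign_register()] result.
#' @param declared_sequence One-letter declared peptide sequence that must
#'   contain the modeled sequence as a contiguous substring.
#' @return A tibble of gaps: `declared_index`, `aa`, `p_pos`, `side`
#'   (`"N"` or `"C"`). Zero rows when everything is modeled.
#' @export
declare_sequence_gap <- function(register, declared_sequence) {
  modeled <- paste(register$aa, collapse = "")
  declared_sequence <- toupper(gsub("\\s", "", declared_sequence))
  at <- regexpr(modeled, declared_sequence, fixed = TRUE)[1]
  if (at < 0) {
    stop("modeled sequence ", modeled,
         " is not a contiguous subsequence of the declared sequence")
  }
  core_start <- attr(register, "core_start", exact = TRUE)
  n_dec <- nchar(declared_sequence)
  dec_idx <- seq_len(n_dec)
  # index of each declared residue along the modeled chain's counting
  pep_index <- dec_idx - (at - 1L)
  modeled_idx <- seq_len(nchar(modeled)) + (at - 1L)
  gaps <- dec_idx[!(dec_idx %in% modeled_idx)]
  if (length(gaps) == 0) {
    return(tibble::tibble(declared_index = integer(), aa = character(),
                          p_pos = integer(), side = character()))
  }
  tibble::tibble(
    declared_index = gaps,
    aa = substring(declared_sequence, gaps, gaps),
    p_pos = p_position(pep_index[gaps], core_start),
    side = ifelse(gaps < at, "N", "C"))
}
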