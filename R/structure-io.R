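# Coordinate-file input: bio3d does the dialect parsing (fixed-column PDB,
# mmCIF atom_site loop); this module reshapes the result into a tidy atom
# table, adds the unit-cell/resolution header bio3d does not expose, infers
# missing element symbols, and applies the altloc policy.

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")
BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

TWO_LETTER_ELEMENTS <- c("FE", "ZN", "MG", "CL", "BR", "MN", "CU", "NI",
                         "CO", "SE", "NA", "CD", "HG", "IOD")

atom_columns <- c("model", "serial", "name", "element", "alt_loc", "res_name",
                  "chain_id", "res_seq", "icode", "x", "y", "z",
                  "occupancy", "b_iso", "het")

new_pfr_structure <- function(atoms, header = empty_header(), source = NA_character_) {
  atoms <- tibble::as_tibble(atoms)
  structure(atoms,
            class = c("pfr_structure", class(tibble::tibble())),
            header = header, source = source)
}

empty_atoms <- function() {
  tibble::tibble(model = integer(), serial = integer(), name = character(),
                 element = character(), alt_loc = character(),
                 res_name = character(), chain_id = character(),
                 res_seq = integer(), icode = character(),
                 x = double(), y = double(), z = double(),
                 occupancy = double(), b_iso = double(), het = logical())
}

empty_header <- function() {
  list(space_group = NA_character_,
       cell_a = NA_real_, cell_b = NA_real_, cell_c = NA_real_,
       cell_alpha = NA_real_, cell_beta = NA_real_, cell_gamma = NA_real_,
       resolution = NA_real_)
}

#' @export
print.pfr_structure <- function(x, ...) {
  h <- structure_header(x)
  nm <- length(unique(x$model))
  cat("# pfr_structure: ", nrow(x), " atoms, ", nm,
      if (nm == 1) " model" else " models", "\n", sep = "")
  if (!is.na(h$cell_a)) {
    cat(sprintf("# cell: a=%.2f b=%.2f c=%.2f  %s\n",
                h$cell_a, h$cell_b, h$cell_c,
                if (is.na(h$space_group)) "" else h$space_group))
  }
  NextMethod()
}

#' Header metadata of a parsed structure
#'
#' @param structure A [read_structure()] result.
#' @return A list with `space_group`, `cell_a`, `cell_b`, `cell_c`,
#'   `cell_alpha`, `cell_beta`, `cell_gamma` (Angstrom / degrees) and
#'   `resolution` (Angstrom, `NA` when the file carries none).
#' @export
structure_header <- function(structure) {
  h <- attr(structure, "header", exact = TRUE)
  if (is.null(h)) empty_header() else h
}

infer_element <- function(name, element, het) {
  element <- toupper(trimws(element))
  name <- toupper(trimws(name))
  missing <- is.na(element) | element == ""
  if (!any(missing)) return(element)
  stripped <- sub("^[0-9']+", "", name[missing])
  two <- substr(stripped, 1, 2)
  guess <- substr(stripped, 1, 1)
  # two-letter symbols only trusted outside polymer atoms, where "CA"/"CD"
  # etc. would collide with carbon naming
  use_two <- het[missing] & two %in% TWO_LETTER_ELEMENTS
  guess[use_two] <- two[use_two]
  element[missing] <- guess
  element
}

validate_atoms <- function(atoms) {
  if (nrow(atoms) == 0) return(atoms)
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) stop("non-finite coordinates at atom serial ",
                     paste(utils::head(atoms$serial[bad], 5), collapse = ", "))
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$occupancy <- pmin(pmax(atoms$occupancy, 0), 1)
  atoms$b_iso[is.na(atoms$b_iso)] <- 0
  if (any(atoms$b_iso < 0)) stop("negative isotropic B-factor in input")
  atoms
}

bio3d_to_atoms <- function(pdb) {
  at <- pdb$atom
  n <- nrow(at)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  blank <- function(v) {
    v <- as.character(v)
    v[is.na(v)] <- ""
    trimws(v)
  }
  one <- tibble::tibble(
    model = 1L,
    serial = as.integer(at$eleno),
    name = blank(at$elety),
    element = blank(at$elesy),
    alt_loc = blank(at$alt),
    res_name = blank(at$resid),
    chain_id = blank(at$chain),
    res_seq = as.integer(at$resno),
    icode = blank(at$insert),
    x = at$x, y = at$y, z = at$z,
    occupancy = as.numeric(at$o),
    b_iso = as.numeric(at$b),
    het = at$type == "HETATM"
  )
  one$element <- infer_element(one$name, one$element, one$het)
  if (n_models == 1L) return(validate_atoms(one))
  frames <- purrr::map(seq_len(n_models), function(m) {
    fr <- one
    co <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    fr$model <- m
    fr$x <- co[, 1]; fr$y <- co[, 2]; fr$z <- co[, 3]
    fr
  })
  validate_atoms(dplyr::bind_rows(frames))
}

parse_pdb_header <- function(lines) {
  h <- empty_header()
  cr <- lines[startsWith(lines, "CRYST1")]
  if (length(cr) >= 1) {
    cr <- cr[1]
    num <- function(from, to) suppressWarnings(as.numeric(substr(cr, from, to)))
    h$cell_a <- num(7, 15);  h$cell_b <- num(16, 24); h$cell_c <- num(25, 33)
    h$cell_alpha <- num(34, 40); h$cell_beta <- num(41, 47); h$cell_gamma <- num(48, 54)
    sg <- trimws(substr(cr, 56, 66))
    if (nzchar(sg)) h$space_group <- sg
  }
  res <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
  if (length(res) >= 1) {
    m <- regmatches(res[1], regexpr("[0-9]+\\.?[0-9]*(?= *ANGSTROM)", res[1], perl = TRUE))
    if (length(m)) h$resolution <- as.numeric(m)
  }
  h
}

cif_scalar <- function(lines, tag) {
  hit <- grep(paste0("^", tag, "\\b"), lines, value = TRUE)
  if (!length(hit)) return(NA_character_)
  val <- trimws(sub(paste0("^", tag, "\\s+"), "", hit[1]))
  gsub("^['\"]|['\"]$", "", val)
}

parse_cif_header <- function(lines) {
  h <- empty_header()
  num <- function(tag) {
    v <- cif_scalar(lines, tag)
    suppressWarnings(as.numeric(sub("\\(.*$", "", v)))
  }
  h$cell_a <- num("_cell\\.length_a")
  h$cell_b <- num("_cell\\.length_b")
  h$cell_c <- num("_cell\\.length_c")
  h$cell_alpha <- num("_cell\\.angle_alpha")
  h$cell_beta <- num("_cell\\.angle_beta")
  h$cell_gamma <- num("_cell\\.angle_gamma")
  sg <- cif_scalar(lines, "_symmetry\\.space_group_name_H-M")
  if (!is.na(sg) && nzchar(sg)) h$space_group <- sg
  h$resolution <- num("_refine\\.ls_d_res_high")
  if (is.na(h$resolution)) h$resolution <- num("_reflns\\.d_resolution_high")
  h
}

validate_header <- function(h) {
  lens <- c(h$cell_a, h$cell_b, h$cell_c)
  angs <- c(h$cell_alpha, h$cell_beta, h$cell_gamma)
  if (any(!is.na(lens) & lens <= 0)) stop("unit-cell lengths must be positive")
  if (any(!is.na(angs) & (angs <= 0 | angs >= 180))) {
    stop("unit-cell angles must lie in (0, 180) degrees")
  }
  h
}

#' Read a coordinate file into a tidy atom table
#'
#' Parses a PDB (fixed-column) or mmCIF (`atom_site` loop) file into a
#' tibble with one row per atom. Multi-model files (`MODEL`/`ENDMDL`
#' blocks) yield one set of rows per model, distinguished by the `model`
#' column and sharing the first model's B-factors and occupancies.
#' Hydrogens, waters and non-polymer HETATM records are retained:
#' downstream analyses select what they need.
#'
#' @param path Path to the coordinate file.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (default: decide from the
#'   file extension, falling back to content sniffing).
#' @param multi Read all models (default `TRUE`); `FALSE` keeps model 1 only.
#' @return A `pfr_structure` tibble with columns `model`, `serial`, `name`,
#'   `element`, `alt_loc`, `res_name`, `chain_id`, `res_seq`, `icode`,
#'   `x`, `y`, `z` (Angstrom), `occupancy`, `b_iso` (Angstrom^2) and `het`.
#'   Header metadata (unit cell, space group, resolution) is available via
#'   [structure_header()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"), multi = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else if (ext %in% c("pdb", "ent", "brk")) "pdb" else {
      first <- readLines(path, n = 1L, warn = FALSE)
      if (length(first) && startsWith(first, "data_")) "mmcif" else "pdb"
    }
  }
  lines <- readLines(path, warn = FALSE)
  parsed <- tryCatch(
    suppressWarnings(
      if (format == "pdb") {
        bio3d::read.pdb(path, multi = multi, verbose = FALSE)
      } else {
        bio3d::read.cif(path, verbose = FALSE)
      }),
    error = function(e) e
  )
  if (inherits(parsed, "error")) {
    has_atoms <- any(grepl(if (format == "pdb") "^(ATOM  |HETATM)" else "^(ATOM|HETATM)\\s", lines))
    if (!has_atoms) {
      warning("no atom records in ", path, "; returning an empty model")
      header <- validate_header(
        if (format == "pdb") parse_pdb_header(lines) else parse_cif_header(lines))
      return(new_pfr_structure(empty_atoms(), header, path))
    }
    stop("failed to parse ", path, " as ", format, ": ", conditionMessage(parsed))
  }
  header <- validate_header(
    if (format == "pdb") parse_pdb_header(lines) else parse_cif_header(lines))
  if (is.null(parsed$atom) || nrow(parsed$atom) == 0) {
    warning("no atom records in ", path, "; returning an empty model")
    return(new_pfr_structure(empty_atoms(), header, path))
  }
  new_pfr_structure(bio3d_to_atoms(parsed), header, path)
}

#' Write an atom table as a PDB file
#'
#' Emits fixed-column ATOM/HETATM records (one `MODEL` block per distinct
#' `model` value when there are several) plus a `CRYST1` record when the
#' header carries a unit cell. Coordinates are written at the format's
#' 3-decimal precision.
#'
#' @param structure Atom table from [read_structure()] or a builder.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  h <- structure_header(structure)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(h$cell_a)) {
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                       h$cell_a, h$cell_b, h$cell_c,
                       h$cell_alpha, h$cell_beta, h$cell_gamma,
                       ifelse(is.na(h$space_group), "P 1", h$space_group)), con)
  }
  models <- sort(unique(structure$model))
  multi <- length(models) > 1
  fmt_name <- function(name, element) {
    ifelse(nchar(name) >= 4 | nchar(element) >= 2,
           formatC(name, width = -4), paste0(" ", formatC(name, width = -3)))
  }
  for (m in models) {
    a <- structure[structure$model == m, , drop = FALSE]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       ifelse(a$het, "HETATM", "ATOM"),
                       a$serial %% 100000L,
                       fmt_name(a$name, a$element), a$alt_loc, a$res_name,
                       a$chain_id, a$res_seq %% 10000L, a$icode,
                       a$x, a$y, a$z, a$occupancy, a$b_iso,
                       formatC(a$element, width = 2)), con)
    writeLines(if (multi) "ENDMDL" else "TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Resolve alternate conformers
#'
#' Reduces an atom table so that each (model, chain, residue, atom name)
#' keeps at most one conformer.
#'
#' @param structure Atom table.
#' @param policy `"highest_occupancy"` (keep the max-occupancy conformer,
#'   ties broken by alphabetical altloc), `"first"` (keep the first record
#'   in file order), or `"strict"` (error if any altloc is present).
#' @return The reduced atom table, same class and attributes.
#' @export
apply_altloc_policy <- function(structure,
                                policy = c("highest_occupancy", "first", "strict")) {
  policy <- match.arg(policy)
  if (nrow(structure) == 0 || all(structure$alt_loc == "")) return(structure)
  if (policy == "strict") {
    bad <- structure[structure$alt_loc != "", c("chain_id", "res_seq", "res_name")]
    bad <- unique(bad)
    stop("alternate conformations present at: ",
         paste(sprintf("%s/%s%d", bad$res_name, bad$chain_id, bad$res_seq),
               collapse = ", "))
  }
  df <- tibble::as_tibble(structure)
  df$.row <- seq_len(nrow(df))
  ord <- if (policy == "highest_occupancy") {
    order(df$model, df$chain_id, df$res_seq, df$icode, df$name,
          -df$occupancy, df$alt_loc, df$.row)
  } else {
    order(df$model, df$chain_id, df$res_seq, df$icode, df$name, df$.row)
  }
  df <- df[ord, , drop = FALSE]
  key <- paste(df$model, df$chain_id, df$res_seq, df$icode, df$name, sep = "\r")
  df <- df[!duplicated(key), , drop = FALSE]
  df <- df[order(df$.row), , drop = FALSE]
  df$.row <- NULL
  new_pfr_structure(df, structure_header(structure),
                    attr(structure, "source", exact = TRUE))
}

#' Per-residue B-factor profile of a chain
#'
#' Averages isotropic B-factors over the selected atoms of every residue in
#' a chain and buckets residues into flexibility categories: `stable`
#' (mean B below 40), `high-flex` (above 80), otherwise `intermediate`.
#' These thresholds mirror common practice for calling a rigidly bound
#' peptide core versus disordered flanks at typical crystallographic
#' resolutions.
#'
#' @param structure Atom table.
#' @param chain Chain identifier.
#' @param selection `"all"` (every non-water heavy atom, default) or
#'   `"backbone"` (N, CA, C, O).
#' @param model Model number to profile (default 1).
#' @return A tibble with one row per residue: `res_seq`, `icode`,
#'   `res_name`, `n_atoms`, `mean_b`, `category`; attributes record the
#'   chain and atom selection used.
#' @export
bfactor_profile <- function(structure, chain, selection = c("all", "backbone"),
                            model = 1L) {
  selection <- match.arg(selection)
  a <- structure[structure$model == model & structure$chain_id == chain &
                   !(structure$res_name %in% WATER_NAMES) &
                   structure$element != "H" & structure$element != "D", , drop = FALSE]
  if (nrow(a) == 0) stop("chain '", chain, "' not found in model ", model)
  if (selection == "backbone") a <- a[a$name %in% c("N", "CA", "C", "O"), , drop = FALSE]
  prof <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(a), .data$res_seq, .data$icode, .data$res_name),
    n_atoms = dplyr::n(),
    mean_b = mean(.data$b_iso),
    .groups = "drop")
  prof <- dplyr::arrange(prof, .data$res_seq, .data$icode)
  prof$category <- dplyr::case_when(
    prof$mean_b < 40 ~ "stable",
    prof$mean_b > 80 ~ "high-flex",
    TRUE ~ "intermediate")
  structure(prof, class = c("pfr_bfactor", class(prof)),
            chain = chain, selection = selection)
}
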