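# End-to-end report bundles. A run configuration collects every tunable in
# one validated list; the two runners execute the crystal-structure and
# trajectory pipelines stage by stage, write TSV tables and JSON reports,
# and record parameters, stage status and any failure in a MANIFEST so a
# partial bundle is always interpretable.

#' Assemble and validate a run configuration
#'
#' Every downstream runner reads its parameters only from this object, and
#' the configuration is serialised verbatim into each report bundle's
#' MANIFEST.
#'
#' @param input Path to the coordinate (or multi-model trajectory) file.
#' @param peptide_chain,receptor_chains Chain assignments.
#' @param core_start 1-based peptide index of the P1 residue.
#' @param declared_sequence Optional declared peptide sequence for gap
#'   reporting.
#' @param vdw_cutoff,hbond_cutoff,polar_cutoff,ca_cutoff,md_contact_cutoff
#'   Distance cutoffs in Angstrom (defaults 4.0, 3.4, 3.6, 7.0, 3.0).
#' @param tolerance Dihedral-window half-width, degrees (default 40).
#' @param cluster_threshold,cluster_linkage Clustering stopping distance
#'   (Angstrom, default 2.5) and linkage (default `"average"`).
#' @param altloc_policy,hydrogen_policy Conformer policy (default
#'   `"highest_occupancy"`) and hydrogen handling for static contacts
#'   (default `"exclude"`; trajectory contacts always follow
#'   `md_hydrogen_policy`, default `"include"`).
#' @param md_hydrogen_policy Hydrogen handling for trajectory contacts.
#' @param turn_start Optional `res_seq` of residue i for the hairpin
#'   window; default: the registered P9 residue.
#' @param reference,reference_chain,reference_res Optional native-structure
#'   comparison: path, chain, and `res_seq` range for [superpose_segments()].
#' @param superpose_atoms Atom pairing for the loop superposition
#'   (default `N, CA, C, O`).
#' @param model Model (ASU copy) to analyse (default 1).
#' @param stride Optional frame stride for trajectory analyses.
#' @param seed Seed echoed into reports (default 1).
#' @param output_dir Directory for the report bundle.
#' @return A validated `pfr_config` list.
#' @export
pfr_config <- function(input, peptide_chain, receptor_chains,
                       core_start, declared_sequence = NULL,
                       vdw_cutoff = 4.0, hbond_cutoff = 3.4,
                       polar_cutoff = 3.6, ca_cutoff = 7.0,
                       md_contact_cutoff = 3.0, tolerance = 40,
                       cluster_threshold = 2.5, cluster_linkage = "average",
                       altloc_policy = "highest_occupancy",
                       hydrogen_policy = "exclude",
                       md_hydrogen_policy = "include",
                       turn_start = NULL,
                       reference = NULL, reference_chain = NULL,
                       reference_res = NULL,
                       superpose_atoms = c("N", "CA", "C", "O"),
                       model = 1L, stride = NULL, seed = 1L,
                       output_dir = "pfr-report") {
  cuts <- c(vdw_cutoff, hbond_cutoff, polar_cutoff, ca_cutoff, md_contact_cutoff,
            cluster_threshold, tolerance)
  if (any(cuts <= 0)) stop("all cutoffs and tolerances must be positive")
  cfg <- list(input = input, peptide_chain = peptide_chain,
              receptor_chains = receptor_chains, core_start = core_start,
              declared_sequence = declared_sequence,
              vdw_cutoff = vdw_cutoff, hbond_cutoff = hbond_cutoff,
              polar_cutoff = polar_cutoff, ca_cutoff = ca_cutoff,
              md_contact_cutoff = md_contact_cutoff, tolerance = tolerance,
              cluster_threshold = cluster_threshold,
              cluster_linkage = cluster_linkage,
              altloc_policy = altloc_policy,
              hydrogen_policy = hydrogen_policy,
              md_hydrogen_policy = md_hydrogen_policy,
              turn_start = turn_start,
              reference = reference, reference_chain = reference_chain,
              reference_res = reference_res, superpose_atoms = superpose_atoms,
              model = model, stride = stride, seed = seed,
              output_dir = output_dir)
  structure(cfg, class = "pfr_config")
}

run_stages <- function(config, stages, bundle_name) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  status <- list()
  results <- list()
  for (nm in names(stages)) {
    res <- tryCatch(stages[[nm]](results), error = function(e) e)
    if (inherits(res, "error")) {
      status[[nm]] <- list(ok = FALSE, error = conditionMessage(res))
      break
    }
    status[[nm]] <- list(ok = TRUE)
    results[[nm]] <- res
  }
  manifest <- list(bundle = bundle_name,
                   config = config[!vapply(config, is.null, logical(1))],
                   stages = status,
                   ok = all(vapply(status, `[[`, logical(1), "ok")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(config$output_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!manifest$ok) {
    failed <- names(status)[!vapply(status, `[[`, logical(1), "ok")]
    stop("stage '", failed[1], "' failed: ", status[[failed[1]]]$error,
         " (partial bundle retained in ", config$output_dir, ")")
  }
  invisible(results)
}

#' Run the full crystal-structure analysis
#'
#' Executes register assignment, contact enumeration and summary, B-factor
#' profiling and hairpin-geometry analysis on a static structure, writing
#' `register.tsv`, `contacts.tsv`, `contact_pairs.json`, `bfactor.tsv`,
#' `turn.json` and, when a native reference is configured,
#' `superposition.json`, plus a `MANIFEST.json` with the configuration and
#' per-stage status. On any stage failure the partial bundle is retained,
#' the MANIFEST marks the failure, and an error is signalled.
#'
#' @param config A [pfr_config()].
#' @return Invisibly, a list of the stage results.
#' @export
run_crystal_analysis <- function(config) {
  out <- config$output_dir
  stages <- list(
    read = function(r) {
      s <- read_structure(config$input)
      apply_altloc_policy(s, config$altloc_policy)
    },
    register = function(r) {
      reg <- assign_register(r$read, config$peptide_chain, config$core_start,
                             model = config$model)
      readr::write_tsv(tibble::as_tibble(reg), file.path(out, "register.tsv"))
      if (!is.null(config$declared_sequence)) {
        gaps <- declare_sequence_gap(reg, config$declared_sequence)
        readr::write_tsv(gaps, file.path(out, "sequence_gaps.tsv"))
      }
      reg
    },
    contacts = function(r) {
      pairs <- find_contacts(r$read, config$peptide_chain,
                             config$receptor_chains,
                             vdw_cutoff = config$vdw_cutoff,
                             hbond_cutoff = config$hbond_cutoff,
                             hydrogen_policy = config$hydrogen_policy,
                             model = config$model)
      tab <- summarize_contacts(pairs, r$register)
      export <- tibble::as_tibble(tab)
      names(export)[names(export) == "vdw"] <- "vdW"
      names(export)[names(export) == "hbond"] <- "H-bonds"
      names(export)[names(export) == "total"] <- "Total"
      readr::write_tsv(export, file.path(out, "contacts.tsv"))
      readr::write_tsv(glance(tab), file.path(out, "contact_totals.tsv"))
      jsonlite::write_json(tibble::as_tibble(pairs),
                           file.path(out, "contact_pairs.json"),
                           auto_unbox = TRUE, digits = NA)
      tab
    },
    bfactor = function(r) {
      prof <- bfactor_profile(r$read, config$peptide_chain, model = config$model)
      readr::write_tsv(tibble::as_tibble(prof), file.path(out, "bfactor.tsv"))
      prof
    },
    turn = function(r) {
      i_res <- config$turn_start
      if (is.null(i_res)) {
        i_res <- r$register$res_seq[match(9L, r$register$p_pos)]
      }
      if (is.na(i_res)) stop("no P9 residue to anchor the turn window")
      ev <- hairpin_evidence(r$read, config$peptide_chain, i_res,
                             hbond_cutoff = config$hbond_cutoff,
                             polar_cutoff = config$polar_cutoff,
                             ca_cutoff = config$ca_cutoff,
                             specs = turn_specs(config$tolerance),
                             model = config$model)
      jsonlite::write_json(tidy(ev), file.path(out, "turn.json"),
                           auto_unbox = TRUE, digits = NA)
      ev
    },
    superpose = function(r) {
      if (is.null(config$reference)) return(NULL)
      ref <- read_structure(config$reference)
      i_res <- config$turn_start
      if (is.null(i_res)) i_res <- r$register$res_seq[match(9L, r$register$p_pos)]
      mob_res <- r$register$res_seq[r$register$res_seq >= i_res][1:4]
      sp <- superpose_segments(r$read, ref,
                               mobile_chain = config$peptide_chain,
                               mobile_res = mob_res,
                               reference_chain = config$reference_chain,
                               reference_res = config$reference_res,
                               atom_names = config$superpose_atoms,
                               mobile_model = config$model)
      jsonlite::write_json(glance(sp), file.path(out, "superposition.json"),
                           auto_unbox = TRUE, digits = NA)
      sp
    })
  run_stages(config, stages, "crystal")
}

#' Run the full trajectory analysis
#'
#' Fits every frame on the receptor Calpha atoms (mass-weighted), then
#' computes the peptide Calpha RMSF profile, per-residue contact
#' fractions, dihedral-window occupancy about the registered P10/P11
#' window, and hierarchical conformational clustering of the peptide;
#' writes `rmsf.tsv`, `contact_fraction.tsv`, `occupancy.json`,
#' `clusters.json` and a `MANIFEST.json`.
#'
#' @param config A [pfr_config()] whose `input` is a multi-model file.
#' @return Invisibly, a list of the stage results.
#' @export
run_traj_analysis <- function(config) {
  out <- config$output_dir
  pc <- config$peptide_chain
  rc <- config$receptor_chains
  stages <- list(
    read = function(r) read_trajectory(config$input),
    fit = function(r) {
      rc_local <- rc
      fit_frames(r$read, chain_id %in% rc_local & name == "CA")
    },
    register = function(r) {
      top <- new_pfr_structure(r$read$topology)
      assign_register(top, pc, config$core_start)
    },
    rmsf = function(r) {
      pc_local <- pc
      prof <- rmsf_profile(r$fit, name == "CA" & chain_id == pc_local)
      readr::write_tsv(tibble::as_tibble(prof), file.path(out, "rmsf.tsv"))
      prof
    },
    contact_fraction = function(r) {
      cf <- traj_contact_fraction(r$fit, pc, rc,
                                  cutoff = config$md_contact_cutoff,
                                  hydrogen_policy = config$md_hydrogen_policy)
      readr::write_tsv(tibble::as_tibble(cf), file.path(out, "contact_fraction.tsv"))
      cf
    },
    occupancy = function(r) {
      reg <- r$register
      i1 <- reg$res_seq[match(10L, reg$p_pos)]
      i2 <- reg$res_seq[match(11L, reg$p_pos)]
      if (is.na(i1) || is.na(i2)) stop("register lacks P10/P11 for the window")
      occ <- dihedral_occupancy(r$fit, pc, i1, i2,
                                specs = turn_specs(config$tolerance))
      jsonlite::write_json(list(joint = occ$joint, n_frames = occ$n_frames,
                                fractions = occ$fractions),
                           file.path(out, "occupancy.json"),
                           auto_unbox = TRUE, digits = NA)
      occ
    },
    clusters = function(r) {
      pc_local <- pc
      cl <- cluster_frames(r$fit, chain_id == pc_local,
                           threshold = config$cluster_threshold,
                           linkage = config$cluster_linkage,
                           stride = config$stride)
      jsonlite::write_json(list(summary = tidy(cl), run = glance(cl)),
                           file.path(out, "clusters.json"),
                           auto_unbox = TRUE, digits = NA)
      cl
    })
  run_stages(config, stages, "trajectory")
}
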