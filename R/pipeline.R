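#' Pipeline configuration
#'
#' Collects every threshold of the screening workflow in one validated
#' object. Defaults are the campaign's printed operating points: novelty
#' exclusion above TC 0.35, clustering at TC 0.5, benchmark deduplication at
#' TC 0.6, property caps MW 400 Da / clogP 4.0 (benchmark MW cap 500 Da),
#' top 0.5% energy cut, 3.5 A polar-contact cutoff, at least 2 key residues
#' contacted, unsatisfied-polar bounds (2 acceptors, 0 donors, combined with
#' "and"), LogAUC lambda 1e-3, and the LRRK2 key-residue list.
#'
#' @param tc_novelty,tc_cluster,tc_dedup Tanimoto thresholds in \[0, 1\].
#' @param mw_max,mw_max_benchmark Molecular-weight caps (Da).
#' @param clogp_max clogP cap.
#' @param energy_top_fraction Fraction of lowest-energy molecules kept by
#'   the post-docking cut, in (0, 1\].
#' @param contact_cutoff Polar-contact distance cutoff (Angstrom).
#' @param min_key_contacts Minimum distinct key residues contacted.
#' @param max_unsat_acceptors,max_unsat_donors Unsatisfied-polar bounds.
#' @param unsat_combine `"and"` or `"or"`.
#' @param lambda LogAUC lower FPR bound.
#' @param strain_threshold Torsion-strain cutoff (used when a strain table is
#'   supplied).
#' @param key_residues A [key_residue_set()].
#' @param seed Integer seed echoed into reports.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(tc_novelty = 0.35, tc_cluster = 0.5, tc_dedup = 0.6,
                            mw_max = 400, mw_max_benchmark = 500, clogp_max = 4.0,
                            energy_top_fraction = 0.005, contact_cutoff = 3.5,
                            min_key_contacts = 2L, max_unsat_acceptors = 2L,
                            max_unsat_donors = 0L, unsat_combine = c("and", "or"),
                            lambda = 1e-3, strain_threshold = 6.0,
                            key_residues = key_residue_set(), seed = 1L) {
  unsat_combine <- match.arg(unsat_combine)
  in01 <- function(x) is.numeric(x) && length(x) == 1L && x >= 0 && x <= 1
  stopifnot(in01(tc_novelty), in01(tc_cluster), in01(tc_dedup),
            mw_max > 0, mw_max_benchmark > 0, clogp_max > 0,
            energy_top_fraction > 0, energy_top_fraction <= 1,
            contact_cutoff > 0, min_key_contacts >= 0,
            max_unsat_acceptors >= 0, max_unsat_donors >= 0,
            lambda > 0, lambda < 1, inherits(key_residues, "key_residue_set"))
  structure(list(tc_novelty = tc_novelty, tc_cluster = tc_cluster,
                 tc_dedup = tc_dedup, mw_max = mw_max,
                 mw_max_benchmark = mw_max_benchmark, clogp_max = clogp_max,
                 energy_top_fraction = energy_top_fraction,
                 contact_cutoff = contact_cutoff,
                 min_key_contacts = as.integer(min_key_contacts),
                 max_unsat_acceptors = as.integer(max_unsat_acceptors),
                 max_unsat_donors = as.integer(max_unsat_donors),
                 unsat_combine = unsat_combine, lambda = lambda,
                 strain_threshold = strain_threshold,
                 key_residues = key_residues, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a key=value file
#'
#' Flat `key = value` lines (`#` comments allowed). Unknown keys are
#' rejected — a misspelled threshold must fail fast, not silently fall back
#' to a default.
#'
#' @param path Config file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[:=]", perl = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = "="), character(1)))
  allowed <- setdiff(names(formals(pipeline_config)), "key_residues")
  bad <- setdiff(keys, allowed)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  args <- lapply(seq_along(keys), function(i) {
    if (keys[i] == "unsat_combine") vals[i] else as.numeric(vals[i])
  })
  names(args) <- keys
  do.call(pipeline_config, args)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in setdiff(names(x), "key_residues")) cat(sprintf("  %s = %s\n", k, format(x[[k]])))
  cat("  key_residues =", paste0(x$key_residues$name, x$key_residues$number, collapse = ", "), "\n")
  invisible(x)
}

#' Benchmark an ensemble of conformers and select the screening structure
#'
#' Runs [rank_conformers()] over a set of per-conformer docking score
#' tables (in memory, or a directory of `<conformer_id>.csv` files) and
#' reports the selected conformer.
#'
#' @param tables Named list of score tables, or a directory path containing
#'   one CSV per conformer.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for `conformer_report.csv` and
#'   per-conformer ROC curves.
#' @return List with `report` (a `conformer_report`) and `selected`
#'   (conformer id).
#' @export
run_benchmark <- function(tables, config = pipeline_config(), out_dir = NULL) {
  if (is.character(tables) && length(tables) == 1L) {
    files <- list.files(tables, pattern = "\\.csv$", full.names = TRUE)
    if (!length(files)) stop("no score tables found in ", tables)
    ids <- sub("\\.csv$", "", basename(files))
    if (anyDuplicated(ids)) stop("duplicate conformer ids in ", tables)
    tables <- stats::setNames(lapply(files, read_score_table), ids)
  }
  report <- rank_conformers(tables, lambda = config$lambda)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(report),
                     file.path(out_dir, "conformer_report.csv"), row.names = FALSE)
    for (cid in names(tables)) {
      write_roc_csv(compute_roc(tables[[cid]]),
                    file.path(out_dir, paste0("roc_", cid, ".csv")))
    }
  }
  list(report = report, selected = report$conformer_id[1])
}

# Post-docking energy cut: keep the floor(n * fraction) lowest energies
# (minimum 1), including every molecule tied at the boundary energy.
energy_top_cut <- function(molecules, fraction) {
  n_keep <- max(1L, floor(nrow(molecules) * fraction))
  ord <- order(molecules$energy, molecules$id)
  boundary <- molecules$energy[ord[n_keep]]
  molecules[molecules$energy <= boundary, ]
}

#' Run the post-docking triage cascade
#'
#' Applies the hit-selection stages in order: top-fraction energy cut,
#' novelty filter against known inhibitors, physicochemical property filter,
#' leader clustering (cluster representatives only advance), key-residue
#' contact filter, unsatisfied-polar filter, and (when a strain table is
#' supplied) the torsion-strain flag. Every molecule receives exactly one
#' audit-trail row recording the last stage it reached and the verdict
#' there; a stage emptying the candidate set is reported, not an error.
#'
#' @param molecules A [molecule_table] with docking energies.
#' @param scenes Named list of [pose_scene()]s covering at least every
#'   molecule id (poses for the docked library).
#' @param references A [molecule_table] of known inhibitors (novelty
#'   reference set).
#' @param config A [pipeline_config()].
#' @param strain_table Optional strain-energy table for [strain_flag()].
#' @param out_dir Optional directory for the audit trail and candidate CSVs.
#' @return An object of class `triage_report`: list with `stage_counts`
#'   (data.frame input/surviving per stage), `trail` (per-molecule verdicts),
#'   `candidates` (final [molecule_table] with `cluster` and closest-reference
#'   columns), and `config`.
#' @export
run_triage <- function(molecules, scenes, references, config = pipeline_config(),
                       strain_table = NULL, out_dir = NULL) {
  stopifnot(inherits(molecules, "molecule_table"))
  missing_scene <- setdiff(molecules$id, names(scenes))
  if (length(missing_scene)) {
    stop("no pose scene for molecule id(s): ",
         paste(utils::head(missing_scene, 5), collapse = ", "),
         if (length(missing_scene) > 5) " ..." else "")
  }
  trail <- data.frame(molecule_id = molecules$id, stage = NA_character_,
                      verdict = NA_character_, detail = NA_character_,
                      stringsAsFactors = FALSE)
  mark <- function(ids, stage, verdict, detail = "") {
    i <- match(ids, trail$molecule_id)
    trail$stage[i] <<- stage
    trail$verdict[i] <<- verdict
    trail$detail[i] <<- detail
  }
  counts <- list()
  note <- function(stage, n_in, n_out) {
    counts[[length(counts) + 1L]] <<- data.frame(stage = stage, input = n_in,
                                                 surviving = n_out)
  }

  # 1. energy cut
  cur <- energy_top_cut(molecules, config$energy_top_fraction)
  dropped <- setdiff(molecules$id, cur$id)
  mark(dropped, "energy_cut", "excluded",
       sprintf("below top %.3g%% by docking energy", 100 * config$energy_top_fraction))
  note("energy_cut", nrow(molecules), nrow(cur))

  # 2. novelty
  nv <- novelty_filter(cur, references, tc_exclude_above = config$tc_novelty)
  mark(nv$excluded$id, "novelty", "excluded",
       sprintf("TC %.3f to %s", nv$excluded$closest_tc, nv$excluded$closest_ref_id))
  note("novelty", nrow(cur), nrow(nv$kept))
  cur <- nv$kept

  # 3. property window
  kept <- property_filter(cur, mw_max = config$mw_max, clogp_max = config$clogp_max)
  out <- cur[!(cur$id %in% kept$id), ]
  mark(out$id, "property", "excluded",
       sprintf("MW %.1f / clogP %.2f outside caps", out$mw, out$clogp))
  note("property", nrow(cur), nrow(kept))
  cur <- kept

  # 4. clustering; representatives advance
  if (nrow(cur)) {
    clusters <- cluster_leader(cur, tc_cut = config$tc_cluster)
    reps <- cluster_representatives(clusters)
    assignment <- attr(clusters, "assignment")
    non_rep <- setdiff(cur$id, reps$id)
    mark(non_rep, "clustering", "excluded",
         sprintf("member of cluster %d (representative %s)",
                 assignment[non_rep],
                 reps$id[assignment[non_rep]]))
    note("clustering", nrow(cur), nrow(reps))
    cur <- reps
  } else {
    note("clustering", 0L, 0L)
  }

  # 5. key-residue contacts
  if (nrow(cur)) {
    pass <- logical(nrow(cur)); cnt <- integer(nrow(cur))
    for (i in seq_len(nrow(cur))) {
      contacts <- detect_polar_contacts(scenes[[cur$id[i]]],
                                        cutoff = config$contact_cutoff)
      v <- key_residue_filter(contacts, keys = config$key_residues,
                              min_contacts = config$min_key_contacts)
      pass[i] <- v; cnt[i] <- attr(v, "count")
    }
    mark(cur$id[!pass], "key_contacts", "excluded",
         sprintf("%d key residue(s) contacted, need %d", cnt[!pass],
                 config$min_key_contacts))
    note("key_contacts", nrow(cur), sum(pass))
    cur <- cur[pass, ]
  } else note("key_contacts", 0L, 0L)

  # 6. unsatisfied polar atoms
  if (nrow(cur)) {
    pass <- logical(nrow(cur)); det <- character(nrow(cur))
    for (i in seq_len(nrow(cur))) {
      u <- count_unsatisfied_polar(scenes[[cur$id[i]]],
                                   contact_cutoff = config$contact_cutoff)
      pass[i] <- unsatisfied_filter(u, config$max_unsat_acceptors,
                                    config$max_unsat_donors,
                                    combine = config$unsat_combine)
      det[i] <- sprintf("%d unsat donor(s), %d unsat acceptor(s)",
                        u[["donors"]], u[["acceptors"]])
    }
    mark(cur$id[!pass], "unsatisfied_polar", "excluded", det[!pass])
    note("unsatisfied_polar", nrow(cur), sum(pass))
    cur <- cur[pass, ]
  } else note("unsatisfied_polar", 0L, 0L)

  # 7. torsion strain (only when a table is supplied)
  if (!is.null(strain_table) && nrow(cur)) {
    pass <- vapply(cur$id, function(id) {
      as.logical(strain_flag(id, strain_table, config$strain_threshold))
    }, logical(1))
    mark(cur$id[!pass], "strain", "excluded", "torsion strain above threshold")
    note("strain", nrow(cur), sum(pass))
    cur <- cur[pass, ]
  }

  mark(cur$id, "final", "selected", "passed all stages")
  stage_counts <- do.call(rbind, counts)
  report <- structure(list(stage_counts = stage_counts, trail = trail,
                           candidates = cur, config = config),
                      class = "triage_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_audit_trail(trail, file.path(out_dir, "audit_trail.csv"))
    utils::write.csv(stage_counts, file.path(out_dir, "stage_counts.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(cur[, setdiff(names(cur), "fp")]),
                     file.path(out_dir, "candidates.csv"), row.names = FALSE)
  }
  report
}

#' @export
print.triage_report <- function(x, ...) {
  cat("<triage_report>\n")
  print.data.frame(x$stage_counts, row.names = FALSE)
  cat(sprintf("final candidates (%d): %s\n", nrow(x$candidates),
              paste(x$candidates$id, collapse = ", ")))
  invisible(x)
}

#' Quantify inhibition for a batch of assayed compounds
#'
#' Fits each compound's dose-response curve, converts IC50 to Ki by
#' Cheng-Prusoff at the supplied assay conditions, and derives the binding
#' free energy. Per-compound convergence failures are flagged in the output
#' and do not stop the batch.
#'
#' @param assay_table Data.frame (`compound_id`, `concentration_uM`,
#'   `activity`) or a CSV path.
#' @param km ATP Michaelis constant (uM) from a titration experiment.
#' @param substrate_conc Assay ATP concentration (uM, default 50).
#' @param fix_hill Passed to [fit_dose_response()].
#' @param out_csv Optional output CSV path.
#' @return Data.frame with one row per compound: `compound_id`, `ic50_uM`,
#'   `hill`, `ki_uM`, `dg_kcal_mol`, `fit_rmse`, `converged`.
#' @export
run_assay <- function(assay_table, km, substrate_conc = 50, fix_hill = NULL,
                      out_csv = NULL) {
  if (is.character(assay_table)) assay_table <- read_assay_csv(assay_table)
  ids <- unique(assay_table$compound_id)
  rows <- lapply(ids, function(id) {
    fit <- fit_dose_response(assay_table[assay_table$compound_id == id, ],
                             fix_hill = fix_hill)
    if (fit$converged) {
      ki <- cheng_prusoff(fit$ic50, substrate_conc = substrate_conc, km = km)
      data.frame(compound_id = id, ic50_uM = fit$ic50, hill = fit$hill,
                 ki_uM = ki, dg_kcal_mol = energy_from_ki(ki),
                 fit_rmse = fit$fit_rmse, converged = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(compound_id = id, ic50_uM = NA_real_, hill = NA_real_,
                 ki_uM = NA_real_, dg_kcal_mol = NA_real_, fit_rmse = NA_real_,
                 converged = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
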