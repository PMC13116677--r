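#' Curate a benchmark active set
#'
#' Reproduces the standard benchmark-curation recipe for enrichment studies:
#' restrict to molecules under a molecular-weight cap, rank by potency
#' (pChEMBL descending, id breaking ties), keep the `n_top` strongest, then
#' make the set non-redundant by a greedy pass from the most potent compound
#' down, discarding any molecule whose ECFP4 Tanimoto coefficient to an
#' already-kept, more potent molecule reaches `dedup_tc`.
#'
#' @param candidates A [molecule_table] with `pchembl` and `mw` populated.
#' @param n_top Number of most potent molecules considered (default 60).
#' @param mw_max Molecular-weight cap in Da, exclusive (default 500).
#' @param dedup_tc Tanimoto redundancy threshold; kept molecules are pairwise
#'   `< dedup_tc` (default 0.6).
#' @return The curated `molecule_table`, ordered by potency.
#' @export
select_benchmark_actives <- function(candidates, n_top = 60L, mw_max = 500,
                                     dedup_tc = 0.6) {
  stopifnot(inherits(candidates, "molecule_table"))
  missing_p <- is.na(candidates$pchembl)
  if (any(missing_p)) {
    warning(sum(missing_p), " molecule(s) skipped: missing pChEMBL (",
            paste(utils::head(candidates$id[missing_p], 5), collapse = ", "), ")")
    candidates <- candidates[!missing_p, ]
  }
  pool <- candidates[candidates$mw < mw_max, ]
  pool <- pool[order(-pool$pchembl, pool$id), ]
  pool <- utils::head(pool, n_top)
  keep <- logical(nrow(pool))
  for (i in seq_len(nrow(pool))) {
    kept_idx <- which(keep)
    ok <- TRUE
    for (j in kept_idx) {
      if (tanimoto(pool$fp[[i]], pool$fp[[j]]) >= dedup_tc) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  pool[keep, ]
}

#' Select property-matched, topologically dissimilar decoys for an active
#'
#' Emulates DUD-E-style decoy selection from a candidate pool: a decoy must
#' match the active's physicochemical profile (molecular weight, clogP,
#' hydrogen-bond donors/acceptors, rotatable bonds within tolerances; net
#' charge exactly) while being topologically dissimilar (ECFP4 Tanimoto to
#' the active below `tc_max_to_active`). Qualifying molecules are returned
#' most-dissimilar first (TC ascending, id breaking ties), up to `n`.
#'
#' @param active A single-row [molecule_table] (or a row index into one).
#' @param pool A [molecule_table] of candidate decoys with properties set.
#' @param n Number of decoys requested (default 50).
#' @param property_tolerances Named list of half-widths: `mw` (Da), `clogp`,
#'   `hbd`, `hba`, `rotatable_bonds`.
#' @param tc_max_to_active Strict upper bound on TC to the active.
#' @return A `molecule_table` of up to `n` decoys; attribute `shortfall`
#'   gives the number missing when the pool cannot supply `n` (also raised
#'   as a warning).
#' @export
match_decoys <- function(active, pool, n = 50L,
                         property_tolerances = list(mw = 25, clogp = 1.0, hbd = 1,
                                                    hba = 2, rotatable_bonds = 2),
                         tc_max_to_active = 0.35) {
  stopifnot(inherits(pool, "molecule_table"), nrow(active) == 1L)
  tol <- property_tolerances
  ok <- abs(pool$mw - active$mw) <= tol$mw &
    abs(pool$clogp - active$clogp) <= tol$clogp &
    abs(pool$hbd - active$hbd) <= tol$hbd &
    abs(pool$hba - active$hba) <= tol$hba &
    abs(pool$rotatable_bonds - active$rotatable_bonds) <= tol$rotatable_bonds &
    pool$net_charge == active$net_charge
  cand <- pool[ok, ]
  if (nrow(cand)) {
    tc <- vapply(cand$fp, tanimoto, numeric(1), b = active$fp[[1]])
    cand <- cand[tc < tc_max_to_active, ]
    tc <- tc[tc < tc_max_to_active]
    ord <- order(tc, cand$id)
    cand <- cand[ord, ]
    cand$tc_to_active <- tc[ord]
  } else {
    cand$tc_to_active <- numeric(0)
  }
  out <- utils::head(cand, n)
  shortfall <- n - nrow(out)
  if (shortfall > 0L) {
    warning("decoy shortfall for active '", active$id, "': ",
            nrow(out), " of ", n, " found")
  }
  attr(out, "shortfall") <- shortfall
  out
}

#' Novelty filter against known inhibitors
#'
#' Splits a candidate set by structural novelty relative to a reference
#' library of known inhibitors: a molecule is excluded iff its maximum ECFP4
#' Tanimoto coefficient over the references strictly exceeds
#' `tc_exclude_above`. Every verdict carries the closest reference and its TC,
#' so the kept set doubles as a closest-known-inhibitor novelty report.
#'
#' @param molecules A [molecule_table] of candidates.
#' @param references A [molecule_table] of known inhibitors.
#' @param tc_exclude_above Exclusion threshold; exclusion is strict (`>`), so
#'   a molecule at exactly the threshold is kept (default 0.35).
#' @return A list with `molecule_table`s `kept` and `excluded`, each carrying
#'   columns `closest_ref_id` and `closest_tc`.
#' @export
novelty_filter <- function(molecules, references, tc_exclude_above = 0.35) {
  stopifnot(inherits(molecules, "molecule_table"))
  if (is.null(references) || nrow(references) == 0L) {
    warning("empty reference set: all molecules kept, novelty not assessed")
    molecules$closest_ref_id <- NA_character_
    molecules$closest_tc <- NA_real_
    return(list(kept = molecules, excluded = molecules[0, ]))
  }
  closest_id <- character(nrow(molecules))
  closest_tc <- numeric(nrow(molecules))
  for (i in seq_len(nrow(molecules))) {
    tcs <- vapply(references$fp, tanimoto, numeric(1), b = molecules$fp[[i]])
    j <- which.max(tcs)
    closest_id[i] <- references$id[j]
    closest_tc[i] <- tcs[j]
  }
  molecules$closest_ref_id <- closest_id
  molecules$closest_tc <- closest_tc
  excl <- closest_tc > tc_exclude_above
  list(kept = molecules[!excl, ], excluded = molecules[excl, ])
}

#' Physicochemical property filter
#'
#' Keeps lead-like molecules: molecular weight at most `mw_max` and clogP at
#' most `clogp_max` (both inclusive; exclusion is for values strictly above
#' the caps).
#'
#' @param molecules A [molecule_table].
#' @param mw_max Molecular-weight cap in Da (default 400).
#' @param clogp_max clogP cap (default 4.0).
#' @return The kept `molecule_table`.
#' @export
property_filter <- function(molecules, mw_max = 400, clogp_max = 4.0) {
  stopifnot(inherits(molecules, "molecule_table"))
  molecules[molecules$mw <= mw_max & molecules$clogp <= clogp_max, ]
}

#' Energy-ordered leader clustering
#'
#' Single-pass leader clustering of docked molecules: molecules are scanned
#' in ascending docking-energy order (ties broken by id); each joins the
#' first existing cluster whose representative it matches at Tanimoto
#' `>= tc_cut`, otherwise it founds a new cluster. Because leaders are seen
#' in energy order, every cluster representative is by construction the
#' lowest-energy member of its cluster, and representatives are pairwise
#' dissimilar (`< tc_cut`).
#'
#' @param molecules A [molecule_table] with `energy` populated.
#' @param tc_cut Cluster membership threshold (default 0.5).
#' @return A list of class `cluster_set`; each element has `representative`
#'   (single-row `molecule_table`) and `members` (`molecule_table`, first row
#'   the representative). The input order's cluster assignment is attached as
#'   attribute `assignment` (named integer vector).
#' @export
cluster_leader <- function(molecules, tc_cut = 0.5) {
  stopifnot(inherits(molecules, "molecule_table"))
  if (any(is.na(molecules$energy))) {
    stop("leader clustering requires a docking energy on every molecule")
  }
  ord <- order(molecules$energy, molecules$id)
  scan <- molecules[ord, ]
  leader_idx <- integer(0)           # row indices into `scan` of leaders
  assign_scan <- integer(nrow(scan))
  for (i in seq_len(nrow(scan))) {
    placed <- FALSE
    for (k in seq_along(leader_idx)) {
      if (tanimoto(scan$fp[[i]], scan$fp[[leader_idx[k]]]) >= tc_cut) {
        assign_scan[i] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      leader_idx <- c(leader_idx, i)
      assign_scan[i] <- length(leader_idx)
    }
  }
  clusters <- lapply(seq_along(leader_idx), function(k) {
    members <- scan[assign_scan == k, ]
    list(representative = scan[leader_idx[k], ], members = members)
  })
  assignment <- assign_scan[order(ord)]
  names(assignment) <- molecules$id
  structure(clusters, assignment = assignment, class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- vapply(x, function(cl) nrow(cl$members), integer(1))
  cat(sprintf("<cluster_set: %d clusters over %d molecules; sizes: %s>\n",
              length(x), sum(sizes), paste(sizes, collapse = " ")))
  invisible(x)
}

#' Representatives of a cluster set
#'
#' @param clusters A `cluster_set` from [cluster_leader()].
#' @return A [molecule_table] of the representatives with a `cluster` column.
#' @export
cluster_representatives <- function(clusters) {
  reps <- do.call(rbind, lapply(clusters, function(cl) cl$representative))
  reps$cluster <- seq_along(clusters)
  class(reps) <- c("molecule_table", "data.frame")
  reps
}

#' Substructure search by SMARTS pattern
#'
#' Returns the library molecules containing the query pattern as a subgraph;
#' used e.g. to retrieve all analogs sharing a hit's scaffold.
#'
#' @param library A [molecule_table].
#' @param scaffold_pattern A SMARTS (or plain SMILES) pattern.
#' @return The matching `molecule_table`, with a `n_matches` column giving
#'   the number of distinct embeddings.
#' @export
substructure_search <- function(library, scaffold_pattern) {
  stopifnot(inherits(library, "molecule_table"),
            is.character(scaffold_pattern), length(scaffold_pattern) == 1L)
  sdf <- smiles_to_sdfset(stats::setNames(library$smiles, library$id), library$id)
  counts <- tryCatch(
    ChemmineR::smartsSearchOB(sdf, scaffold_pattern, uniqueMatches = TRUE),
    error = function(e) stop("invalid SMARTS pattern '", scaffold_pattern, "': ",
                             conditionMessage(e))
  )
  hits <- library[counts > 0, ]
  hits$n_matches <- as.integer(counts[counts > 0])
  hits
}

#' Write a filter audit trail to CSV
#'
#' @param trail A data.frame with columns `molecule_id`, `stage`, `verdict`,
#'   `detail` (as produced by [run_triage()]).
#' @param path Output CSV path.
#' @export
write_audit_trail <- function(trail, path) {
  utils::write.csv(trail, path, row.names = FALSE)
  invisible(path)
}
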