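#' ROC curve from docking score records
#'
#' Builds the receiver operating characteristic curve of a docking run on a
#' benchmark of known actives and decoys. Records are ranked by energy
#' ascending (lower docking energy = better). Tied energies advance the true-
#' and false-positive rates jointly, i.e. each tie group contributes a single
#' diagonal step — the Mann-Whitney convention that credits half a pair for
#' ties.
#'
#' @param records A data.frame with columns `molecule_id`, `label` (values
#'   `"active"`/`"decoy"`), `energy` (kcal/mol, finite).
#' @return A list of class `roc_curve` with nondecreasing numeric vectors
#'   `fpr` and `tpr` (both starting at 0 and ending at 1) and the counts
#'   `n_actives`, `n_decoys`.
#' @export
compute_roc <- function(records) {
  stopifnot(is.data.frame(records), all(c("label", "energy") %in% names(records)))
  if (!all(records$label %in% c("active", "decoy"))) {
    stop("labels must be 'active' or 'decoy'")
  }
  if (!all(is.finite(records$energy))) stop("energies must be finite")
  n_act <- sum(records$label == "active")
  n_dec <- sum(records$label == "decoy")
  if (n_act == 0L || n_dec == 0L) {
    stop("enrichment is undefined without at least one active and one decoy")
  }
  ord <- order(records$energy)
  lab <- records$label[ord]
  en <- records$energy[ord]
  # one step per tie group
  grp <- cumsum(!duplicated(en))
  act_steps <- tapply(lab == "active", grp, sum)
  dec_steps <- tapply(lab == "decoy", grp, sum)
  tpr <- c(0, cumsum(act_steps) / n_act)
  fpr <- c(0, cumsum(dec_steps) / n_dec)
  structure(list(fpr = as.numeric(fpr), tpr = as.numeric(tpr),
                 n_actives = n_act, n_decoys = n_dec),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve: %d points, %d actives / %d decoys, AUC %.1f%%>\n",
              length(x$fpr), x$n_actives, x$n_decoys, auc_percent(x)))
  invisible(x)
}

#' Plot a ROC curve
#'
#' @param x A `roc_curve`.
#' @param log_x Plot the false-positive axis on a log10 scale (emphasizes
#'   early enrichment).
#' @param lambda Lower axis limit used when `log_x = TRUE`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.roc_curve <- function(x, log_x = FALSE, lambda = 1e-3, ...) {
  fpr <- x$fpr
  if (log_x) fpr <- pmax(fpr, lambda)
  graphics::plot(fpr, x$tpr, type = "l", log = if (log_x) "x" else "",
                 xlab = "False positive rate", ylab = "True positive rate", ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

check_roc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve") || (is.list(curve) && all(c("fpr", "tpr") %in% names(curve))))
  fpr <- curve$fpr; tpr <- curve$tpr
  stopifnot(length(fpr) == length(tpr), length(fpr) >= 2,
            !is.unsorted(fpr), !is.unsorted(tpr),
            all(fpr >= 0 & fpr <= 1), all(tpr >= 0 & tpr <= 1))
  invisible(curve)
}

#' Area under the ROC curve, in percent
#'
#' Trapezoidal area times 100. Equivalent to the Mann-Whitney U statistic
#' divided by `n_actives * n_decoys` (with half credit for energy ties),
#' expressed as a percentage: 100 = perfect ranking, 50 = random.
#'
#' @param curve A `roc_curve` (from [compute_roc()]).
#' @return AUC in percent.
#' @export
auc_percent <- function(curve) {
  check_roc(curve)
  x <- curve$fpr; y <- curve$tpr
  100 * sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Early-enrichment LogAUC, in percent
#'
#' Area under the ROC curve with the false-positive axis rescaled to
#' log10 over `[lambda, 1]` (three decades for the default
#' `lambda = 1e-3`), normalized by the number of decades, baseline-corrected
#' by the printed random-enrichment constant 0.145, and expressed in percent.
#' A perfect ranking scores 100 x (1 - 0.145) = 85.5; random ranking scores
#' approximately 0.
#'
#' Between curve points TPR is treated exactly as the ROC step/tie geometry
#' dictates: vertical segments contribute nothing, horizontal plateaus are
#' integrated as constants, and tie-group diagonal segments are integrated
#' analytically as linear ramps. FPR values below `lambda` are clamped to
#' `lambda` before the transform (their log-width is zero).
#'
#' @param curve A `roc_curve`.
#' @param lambda Lower bound of the log-rescaled FPR axis, in (0, 1).
#' @param baseline Random-enrichment constant subtracted after normalization.
#' @return LogAUC in percent.
#' @export
logauc_percent <- function(curve, lambda = 1e-3, baseline = 0.145) {
  check_roc(curve)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0 || lambda >= 1) {
    stop("lambda must lie strictly between 0 and 1")
  }
  decades <- -log10(lambda)
  area <- log_roc_area(curve$fpr, curve$tpr, lambda)
  100 * (area / decades - baseline)
}

# \int_{lambda}^{1} TPR(x) dlog10(x) over a piecewise-linear ROC polyline.
# For a segment (x1,y1)-(x2,y2) with y = a + b x:
#   \int y dlog10 x = (1/ln 10) [ a ln x + b x ]
log_roc_area <- function(fpr, tpr, lambda) {
  area <- 0
  ln10 <- log(10)
  for (i in seq_len(length(fpr) - 1L)) {
    x1 <- fpr[i]; x2 <- fpr[i + 1L]
    if (x2 <= lambda || x2 == x1) next
    y1 <- tpr[i]; y2 <- tpr[i + 1L]
    b <- (y2 - y1) / (x2 - x1)
    a <- y1 - b * x1
    lo <- max(x1, lambda)
    area <- area + (a * log(x2 / lo) + b * (x2 - lo)) / ln10
  }
  area
}

#' Score an ensemble of receptor conformers and pick the screening structure
#'
#' For each conformer's docking table the function computes AUC, LogAUC, the
#' mean docking energy of the actives, and the active/decoy separation (mean
#' decoy energy minus mean active energy; larger = actives better
#' discriminated). Conformers are ranked on each metric and the report is
#' sorted by LogAUC descending (ties: AUC descending, then conformer id), so
#' the first row is the selected screening structure.
#'
#' @param tables Named list mapping conformer id to a score table accepted by
#'   [compute_roc()]. All tables must cover the same molecule id set.
#' @param lambda Passed to [logauc_percent()].
#' @return A data.frame of class `conformer_report` with one row per
#'   conformer, metric columns, and rank columns `rank_by_logauc`,
#'   `rank_by_mean_active_energy`, `rank_by_separation` (each a permutation
#'   of 1..n).
#' @export
rank_conformers <- function(tables, lambda = 1e-3) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  ids <- names(tables)
  if (is.null(ids) || any(!nzchar(ids))) stop("tables must be named by conformer id")
  if (anyDuplicated(ids)) stop("duplicate conformer ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ref_ids <- sort(tables[[1]]$molecule_id)
  metrics <- lapply(ids, function(cid) {
    tab <- tables[[cid]]
    if (!identical(sort(tab$molecule_id), ref_ids)) {
      stop("conformer '", cid, "' covers a different molecule set; metrics would not be comparable")
    }
    roc <- compute_roc(tab)
    mean_act <- mean(tab$energy[tab$label == "active"])
    mean_dec <- mean(tab$energy[tab$label == "decoy"])
    data.frame(conformer_id = cid,
               auc = auc_percent(roc),
               logauc = logauc_percent(roc, lambda = lambda),
               mean_active_energy = mean_act,
               separation = mean_dec - mean_act,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, metrics)
  # deterministic dense ranks: metric first, conformer id breaks ties
  rep$rank_by_logauc <- order(order(-rep$logauc, rep$conformer_id))
  rep$rank_by_mean_active_energy <- order(order(rep$mean_active_energy, rep$conformer_id))
  rep$rank_by_separation <- order(order(-rep$separation, rep$conformer_id))
  rep <- rep[order(-rep$logauc, -rep$auc, rep$conformer_id), ]
  rownames(rep) <- NULL
  class(rep) <- c("conformer_report", "data.frame")
  rep
}

#' @export
print.conformer_report <- function(x, ...) {
  cat(sprintf("<conformer_report: %d conformers; selected: %s (LogAUC %.1f%%, AUC %.1f%%)>\n",
              nrow(x), x$conformer_id[1], x$logauc[1], x$auc[1]))
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}

#' Read a docking score table from CSV
#'
#' Expected columns: `molecule_id`, `label` (active/decoy), `energy`.
#'
#' @param path CSV path.
#' @return A data.frame of score records.
#' @export
read_score_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecule_id", "label", "energy")
  if (!all(need %in% names(tab))) {
    stop("score table ", path, " must have columns: ", paste(need, collapse = ", "))
  }
  tab$molecule_id <- as.character(tab$molecule_id)
  tab$energy <- as.numeric(tab$energy)
  tab
}

#' Write a docking score table to CSV
#'
#' @param records Score records data.frame.
#' @param path Output CSV path.
#' @export
write_score_table <- function(records, path) {
  utils::write.csv(records[, c("molecule_id", "label", "energy")], path, row.names = FALSE)
  invisible(path)
}

#' Write a ROC curve as a two-column CSV
#'
#' @param curve A `roc_curve`.
#' @param path Output CSV path.
#' @export
write_roc_csv <- function(curve, path) {
  utils::write.csv(data.frame(fpr = curve$fpr, tpr = curve$tpr), path, row.names = FALSE)
  invisible(path)
}
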