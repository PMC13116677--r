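#' Fit the Michaelis-Menten equation to a substrate titration
#'
#' Nonlinear least-squares fit of `v = Vmax * S / (Km + S)`, initialized at
#' `Vmax = max(v)` and Km at the substrate concentration of half-maximal
#' velocity (linearly interpolated). Used to determine the ATP Km feeding
#' the Cheng-Prusoff conversion.
#'
#' @param substrate_conc Substrate concentrations (uM, >= 3 distinct values).
#' @param velocity Observed velocities (>= 0).
#' @return An object of class `mm_fit`: list with `km`, `vmax`, `fit_rmse`,
#'   `converged`, and the underlying `nls` fit (`NULL` on failure).
#' @export
fit_michaelis_menten <- function(substrate_conc, velocity) {
  stopifnot(length(substrate_conc) == length(velocity),
            length(unique(substrate_conc)) >= 3, all(velocity >= 0))
  df <- data.frame(S = substrate_conc, v = velocity)
  vmax0 <- max(df$v)
  half <- vmax0 / 2
  km0 <- tryCatch(stats::approx(df$v, df$S, xout = half, ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(df$S)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), data = df,
                      start = list(Vmax = vmax0, Km = km0),
                      lower = c(Vmax = 0, Km = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(km = NA_real_, vmax = NA_real_, fit_rmse = NA_real_,
                          converged = FALSE, fit = NULL), class = "mm_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(km = unname(cf["Km"]), vmax = unname(cf["Vmax"]),
                 fit_rmse = sqrt(mean(stats::residuals(fit)^2)),
                 converged = TRUE, fit = fit),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("Michaelis-Menten fit: Km = %.4g uM, Vmax = %.4g (RMSE %.3g)\n",
                x$km, x$vmax, x$fit_rmse))
  } else cat("Michaelis-Menten fit: did not converge\n")
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) c(Km = object$km, Vmax = object$vmax)

#' @export
predict.mm_fit <- function(object, substrate_conc, ...) {
  object$vmax * substrate_conc / (object$km + substrate_conc)
}

#' Fit a dose-response curve and estimate IC50
#'
#' Least-squares fit of the logistic inhibition model
#' `a = 1 / (1 + (c / IC50)^h)` to normalized activities (0-1 scale) against
#' inhibitor concentration. IC50 is fitted on the log scale for stability,
#' initialized at the concentration whose observed activity is nearest 0.5,
#' with Hill slope h starting at 1 (optionally fixed there). A table with no
#' observable transition (all activities above 0.8 or all below 0.2) is
#' flagged non-converged rather than extrapolated.
#'
#' @param table A dose-response data.frame with columns `concentration_uM`
#'   and `activity` (a `compound_id` column is carried through if present).
#' @param fix_hill Fix the Hill slope at this value instead of fitting it
#'   (e.g. `fix_hill = 1`); `NULL` (default) fits the slope.
#' @return An object of class `dose_response_fit`: list with `ic50`, `hill`,
#'   `fit_rmse`, `converged`, `compound_id`, `data`, and the optimizer result.
#' @export
fit_dose_response <- function(table, fix_hill = NULL) {
  stopifnot(all(c("concentration_uM", "activity") %in% names(table)))
  cid <- if ("compound_id" %in% names(table)) table$compound_id[1] else NA_character_
  df <- data.frame(conc = table$concentration_uM, a = table$activity)
  pos <- df[df$conc > 0, ]
  fail <- function() structure(list(ic50 = NA_real_, hill = NA_real_,
                                    fit_rmse = NA_real_, converged = FALSE,
                                    compound_id = cid, data = df, fit = NULL),
                               class = "dose_response_fit")
  if (length(unique(pos$conc)) < 4) return(fail())
  if (all(df$a > 0.8) || all(df$a < 0.2)) return(fail())
  ic50_0 <- pos$conc[which.min(abs(pos$a - 0.5))]
  resid_fn <- function(p) {
    h <- if (is.null(fix_hill)) p[2] else fix_hill
    1 / (1 + (pos$conc / exp(p[1]))^h) - pos$a
  }
  # Levenberg-Marquardt with bound constraints on the Hill slope; a couple of
  # shifted restarts guard against a degenerate Jacobian at the first guess
  best <- NULL
  for (shift in c(0, 1, -1)) {
    p0 <- if (is.null(fix_hill)) c(log(ic50_0) + shift, 1) else log(ic50_0) + shift
    lo <- if (is.null(fix_hill)) c(-Inf, 0.05) else -Inf
    hi <- if (is.null(fix_hill)) c(Inf, 10) else Inf
    out <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lo, upper = hi, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(out) || !(out$info %in% 1:4)) next
    if (is.null(best) || out$deviance < best$deviance) best <- out
  }
  if (is.null(best)) return(fail())
  structure(list(ic50 = exp(best$par[1]),
                 hill = if (is.null(fix_hill)) best$par[2] else fix_hill,
                 fit_rmse = sqrt(mean(best$fvec^2)),
                 converged = TRUE, compound_id = cid, data = df, fit = best),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("Dose-response fit%s: IC50 = %.4g uM, Hill = %.3g (RMSE %.3g)\n",
                if (is.na(x$compound_id)) "" else paste0(" [", x$compound_id, "]"),
                x$ic50, x$hill, x$fit_rmse))
  } else cat("Dose-response fit: did not converge (no transition in range?)\n")
  invisible(x)
}

#' @export
coef.dose_response_fit <- function(object, ...) c(ic50 = object$ic50, hill = object$hill)

#' @export
predict.dose_response_fit <- function(object, concentration_uM, ...) {
  1 / (1 + (concentration_uM / object$ic50)^object$hill)
}

#' @export
plot.dose_response_fit <- function(x, ...) {
  df <- x$data[x$data$conc > 0, ]
  graphics::plot(df$conc, df$a, log = "x", xlab = "Concentration (uM)",
                 ylab = "Relative activity", ylim = c(0, max(1, df$a)), ...)
  if (x$converged) {
    cc <- 10^seq(log10(min(df$conc)), log10(max(df$conc)), length.out = 200)
    graphics::lines(cc, predict(x, cc))
  }
  invisible(x)
}

#' Cheng-Prusoff conversion of IC50 to Ki
#'
#' For a competitive inhibitor assayed at substrate concentration `[S]`
#' against a Michaelis constant `Km`:
#' `Ki = IC50 / (1 + [S] / Km)`.
#'
#' @param ic50 Fitted IC50 (uM, > 0).
#' @param substrate_conc Substrate (ATP) concentration in the assay (uM,
#'   >= 0; default 50).
#' @param km Michaelis constant of the substrate (uM, > 0); no default — it
#'   must come from a titration experiment (see [fit_michaelis_menten()]).
#' @return Ki in uM.
#' @export
cheng_prusoff <- function(ic50, substrate_conc = 50, km) {
  if (any(km <= 0)) stop("km must be positive")
  stopifnot(all(ic50 > 0), all(substrate_conc >= 0))
  ic50 / (1 + substrate_conc / km)
}

# Gas constant in kcal/(mol K)
R_KCAL <- 0.0019872

#' Binding free energy from an inhibition constant
#'
#' `dG = R T ln(Ki)` with Ki expressed in mol/L (standard-state 1 M), giving
#' kcal/mol; a ten-fold potency gain deepens dG by RT ln 10 ~ 1.364 kcal/mol
#' at 298.15 K.
#'
#' @param ki Inhibition constant in uM (> 0).
#' @param temperature Kelvin (default 298.15).
#' @return Free energy in kcal/mol (negative for sub-molar Ki).
#' @export
energy_from_ki <- function(ki, temperature = 298.15) {
  if (any(ki <= 0)) stop("ki must be positive")
  R_KCAL * temperature * log(ki * 1e-6)
}

#' Correlate experimental and predicted binding energies
#'
#' Pearson correlation with the two-sided p-value from the t distribution on
#' n - 2 degrees of freedom (via [stats::cor.test()]). Being scale- and
#' offset-invariant, the correlation is insensitive to the unit convention
#' of the predicted energies.
#'
#' @param experimental,predicted Equal-length numeric vectors (n >= 3) of
#'   binding energies (kcal/mol).
#' @return List with `pearson_r`, `p_value`, `n`.
#' @export
correlate_energies <- function(experimental, predicted) {
  stopifnot(length(experimental) == length(predicted), length(experimental) >= 3,
            all(is.finite(experimental)), all(is.finite(predicted)))
  if (stats::sd(experimental) == 0 || stats::sd(predicted) == 0) {
    stop("correlation undefined: zero variance")
  }
  ct <- stats::cor.test(experimental, predicted, method = "pearson")
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
       n = length(experimental))
}

#' Read an assay table from CSV
#'
#' Expected columns: `compound_id`, `concentration_uM`, `activity`, and
#' optionally `replicate`.
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_assay_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "concentration_uM", "activity")
  if (!all(need %in% names(tab))) {
    stop("assay table must have columns: ", paste(need, collapse = ", "))
  }
  tab
}

#' Min-max normalization of assay activities
#'
#' Rescales raw signals to the 0-1 activity scale. Off by default in the
#' pipeline: activities are normally expected pre-normalized.
#'
#' @param signal Raw signal vector.
#' @return Normalized vector in \[0, 1\].
#' @export
normalize_activity <- function(signal) {
  rng <- range(signal)
  if (diff(rng) == 0) stop("cannot normalize a constant signal")
  (signal - rng[1]) / diff(rng)
}
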