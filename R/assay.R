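#' One differentiation experiment for one compound
#'
#' Embryoid bodies are plated one per well (24-well plates by default) and
#' scored dichotomously for the presence of contracting cardiomyocytes.
#'
#' @param compound_id Compound identifier.
#' @param experiment_id Experiment identifier.
#' @param concentration Concentrations in uM; must include 0 (solvent
#'   control) exactly once.
#' @param wells_total Wells scored per concentration (default 24).
#' @param wells_contracting Wells with contracting cardiomyocytes,
#'   `0 <= wells_contracting <= wells_total`.
#' @return Object of class `differentiation_run`.
#' @examples
#' differentiation_run("x", "e1", c(0, 5, 20), 24, c(23, 14, 3))
#' @export
differentiation_run <- function(compound_id, experiment_id, concentration,
                                wells_total = 24, wells_contracting) {
  n <- length(concentration)
  wells_total <- rep_len(wells_total, n)
  if (length(wells_contracting) != n) {
    stop("'wells_contracting' must match 'concentration' in length",
         call. = FALSE)
  }
  if (sum(concentration == 0) != 1L) {
    stop("exactly one solvent-control (0 uM) entry is required",
         call. = FALSE)
  }
  if (any(wells_contracting < 0) || any(wells_contracting > wells_total)) {
    stop("0 <= wells_contracting <= wells_total violated", call. = FALSE)
  }
  ord <- order(concentration)
  structure(
    data.frame(concentration = concentration[ord],
               wells_total = wells_total[ord],
               wells_contracting = wells_contracting[ord]),
    compound_id = as.character(compound_id),
    experiment_id = as.character(experiment_id),
    class = c("differentiation_run", "data.frame")
  )
}

#' Quality gate on a differentiation run
#'
#' A run is accepted when the solvent control shows contracting
#' cardiomyocytes in at least 21 of 24 wells; for other plate sizes the
#' rule scales proportionally to `ceiling(21/24 x wells_total)`.
#'
#' @param run A [differentiation_run()].
#' @return List with `accepted` (logical) and `reason` (text).
#' @examples
#' r <- differentiation_run("x", "e1", c(0, 5), 24, c(21, 10))
#' accept_differentiation_run(r)$accepted # TRUE
#' @export
accept_differentiation_run <- function(run) {
  stopifnot(inherits(run, "differentiation_run"))
  ctrl <- run[run$concentration == 0, ]
  if (nrow(ctrl) != 1L) stop("missing solvent-control entry", call. = FALSE)
  need <- ceiling(21 / 24 * ctrl$wells_total)
  ok <- ctrl$wells_contracting >= need
  list(
    accepted = ok,
    reason = sprintf("control %d/%d contracting (threshold %d): %s",
                     ctrl$wells_contracting, ctrl$wells_total, need,
                     if (ok) "accepted" else "rejected")
  )
}

#' Pool differentiation runs into a quantal dataset
#'
#' Applies the control-based quality gate to each run, pools the accepted
#' runs of one compound by summing wells per concentration (preserving the
#' binomial structure for likelihood fitting), and recodes the outcome as
#' affected = non-contracting wells.
#'
#' @param runs List of [differentiation_run()] objects, all for the same
#'   compound.
#' @param apply_gate Apply [accept_differentiation_run()] and drop rejected
#'   runs (default `TRUE`); rejections are reported via a message.
#' @return A [quantal_dataset()].
#' @examples
#' r1 <- differentiation_run("x", "e1", c(0, 5), 24, c(23, 10))
#' r2 <- differentiation_run("x", "e2", c(0, 5), 24, c(22, 12))
#' to_quantal(list(r1, r2))
#' @export
to_quantal <- function(runs, apply_gate = TRUE) {
  stopifnot(length(runs) >= 1)
  ids <- vapply(runs, function(r) attr(r, "compound_id"), character(1))
  if (length(unique(ids)) != 1L) {
    stop("runs mix compounds: ", paste(unique(ids), collapse = ", "),
         call. = FALSE)
  }
  if (apply_gate) {
    verdicts <- lapply(runs, accept_differentiation_run)
    keep <- vapply(verdicts, `[[`, logical(1), "accepted")
    if (any(!keep)) {
      dropped <- vapply(runs[!keep], function(r) attr(r, "experiment_id"),
                        character(1))
      message("excluded run(s) failing the control gate: ",
              paste(dropped, collapse = ", "))
    }
    runs <- runs[keep]
    if (!length(runs)) stop("no run passed the control gate", call. = FALSE)
  }
  pooled <- do.call(rbind, lapply(runs, as.data.frame))
  agg <- stats::aggregate(cbind(wells_total, wells_contracting) ~
                            concentration, data = pooled, FUN = sum)
  quantal_dataset(ids[1], agg$concentration, agg$wells_total,
                  agg$wells_total - agg$wells_contracting)
}

#' Normalise viability absorbances to percent of solvent control
#'
#' @param absorbances Raw absorbance values (numeric vector).
#' @param solvent_control_absorbance Mean absorbance of the solvent
#'   control; must be > 0.
#' @return Viability in percent of control, same length as `absorbances`.
#' @examples
#' normalize_viability(c(1.0, 0.1), 1.0) # 100, 10
#' @export
normalize_viability <- function(absorbances, solvent_control_absorbance) {
  if (!is.numeric(solvent_control_absorbance) ||
      length(solvent_control_absorbance) != 1L ||
      solvent_control_absorbance <= 0) {
    stop("solvent-control absorbance must be a single positive number",
         call. = FALSE)
  }
  100 * absorbances / solvent_control_absorbance
}

#' Four-parameter logistic fit of a concentration-response curve
#'
#' Least-squares fit of `r(d) = bottom + (top - bottom) /
#' (1 + (d/ec50)^hill)` via Levenberg-Marquardt (`minpack.lm::nlsLM`).
#' Used for curve display and viability interpolation only — benchmark
#' concentrations are always derived from the quantal model suite, never
#' from this curve. Zero concentrations are dropped from the fit (the 4PL
#' is undefined at d = 0 for non-integer hill; the control level informs
#' `top` through the normalisation instead).
#'
#' @param concentrations Concentrations in uM.
#' @param responses Responses (e.g. percent viability), same length.
#' @return List with `bottom`, `top`, `ec50`, `hill`, `converged` and
#'   `flag` (`NA` or a text describing a degenerate fit).
#' @examples
#' d <- c(1, 3, 10, 30, 60)
#' r <- 5 + (100 - 5) / (1 + (d / 15)^2)
#' fit_4pl(d, r)
#' @export
fit_4pl <- function(concentrations, responses) {
  keep <- concentrations > 0
  d <- concentrations[keep]
  r <- responses[keep]
  if (length(unique(d)) < 4) {
    stop("need at least 4 distinct positive concentrations", call. = FALSE)
  }
  if (stats::sd(r) < 1e-8) {
    return(list(bottom = mean(r), top = mean(r), ec50 = NA_real_,
                hill = NA_real_, converged = FALSE,
                flag = "flat response: hill/ec50 unidentifiable"))
  }
  start <- list(bottom = min(r), top = max(r),
                ec50 = stats::median(d), hill = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      r ~ bottom + (top - bottom) / (1 + (d / ec50)^hill),
      start = start,
      lower = c(bottom = -Inf, top = -Inf, ec50 = 1e-9, hill = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(bottom = NA_real_, top = NA_real_, ec50 = NA_real_,
                hill = NA_real_, converged = FALSE,
                flag = "4PL fit did not converge"))
  }
  cf <- stats::coef(fit)
  list(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
       ec50 = unname(cf["ec50"]), hill = unname(cf["hill"]),
       converged = TRUE, flag = NA_character_)
}

#' Viability curve for one compound and exposure duration
#'
#' @param compound_id Compound identifier.
#' @param exposure_days Exposure duration in days (1 or 5 in the standard
#'   design).
#' @param concentration Concentrations in uM.
#' @param viability_percent Viability as percent of solvent control.
#' @param fit Fit the 4PL on construction (default `TRUE`).
#' @return Object of class `viability_curve`: list with the data and,
#'   when fitted, the 4PL parameters.
#' @export
viability_curve <- function(compound_id, exposure_days, concentration,
                            viability_percent, fit = TRUE) {
  if (any(viability_percent < 0)) {
    stop("viability must be >= 0", call. = FALSE)
  }
  ord <- order(concentration)
  obj <- list(compound_id = as.character(compound_id),
              exposure_days = exposure_days,
              concentration = concentration[ord],
              viability_percent = viability_percent[ord],
              fit = NULL)
  if (fit) {
    obj$fit <- tryCatch(fit_4pl(concentration, viability_percent),
                        error = function(e) NULL)
  }
  structure(obj, class = "viability_curve")
}

# viability at a concentration: 4PL if available, else linear interpolation;
# outside the tested range the nearest bound is used with a warning
viability_at <- function(curve, conc) {
  rng <- range(curve$concentration)
  clamped <- min(max(conc, rng[1]), rng[2])
  if (clamped != conc) {
    warning(sprintf(
      "concentration %.3g uM outside tested range [%.3g, %.3g]; evaluated at %.3g",
      conc, rng[1], rng[2], clamped), call. = FALSE)
  }
  f <- curve$fit
  if (!is.null(f) && isTRUE(f$converged)) {
    if (clamped <= 0) return(f$top)
    return(f$bottom + (f$top - f$bottom) / (1 + (clamped / f$ec50)^f$hill))
  }
  stats::approx(curve$concentration, curve$viability_percent,
                xout = clamped, rule = 2)$y
}

#' Check that a BMC lies in the non-cytotoxic range
#'
#' Interpolates each supplied viability curve at the BMC and passes when
#' viability is at least `threshold` percent for every exposure duration.
#' A BMC outside the tested concentration range is evaluated at the
#' nearest bound with a warning (extrapolation).
#'
#' @param bmc Benchmark concentration in uM.
#' @param curves A [viability_curve()] or list of them (e.g. 1-day and
#'   5-day exposure).
#' @param threshold Minimum viability in percent (default 80).
#' @return List with `pass` (logical), `viability` (named by exposure
#'   days) and `messages`.
#' @export
cytotoxicity_guard <- function(bmc, curves, threshold = 80) {
  if (inherits(curves, "viability_curve")) curves <- list(curves)
  viab <- vapply(curves, viability_at, numeric(1), conc = bmc)
  names(viab) <- vapply(curves, function(c) paste0(c$exposure_days, "d"),
                        character(1))
  pass <- all(viab >= threshold)
  msgs <- sprintf("viability at BMC (%.3g uM), %s exposure: %.1f%% (%s %g%%)",
                  bmc, names(viab), viab,
                  ifelse(viab >= threshold, ">=", "<"), threshold)
  list(pass = pass, viability = viab, messages = msgs)
}
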