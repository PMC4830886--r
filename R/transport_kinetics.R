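#' Sampling-corrected cumulative transported amounts
#'
#' Converts measured receiver concentrations into the cumulative amount of
#' compound that has crossed the cell layer up to each sampling time,
#' compensating for the analyte removed at earlier samplings. Because each
#' sampling withdraws `sample_volume` ml and replaces it with blank buffer,
#' the measured concentration at time k reflects only what remains in the
#' receiver; the cumulative transported amount is
#'
#' \deqn{Q_k = c_k V_b + V_s \sum_{j<k} c_j}
#'
#' i.e. the amount currently present plus every previously withdrawn
#' aliquot. Summing over all earlier aliquots (not just the immediately
#' preceding one) is the closed form of applying the one-step correction
#' recursively.
#'
#' @param tc A [transport_timecourse()].
#' @param cfg A [transwell_config()].
#' @return Numeric vector of cumulative amounts in nmol, one per sampling
#'   time.
#' @examples
#' cfg <- transwell_config()
#' tc <- transport_timecourse("x", "r1", c(15, 30), c(1.0, 1.8))
#' corrected_cumulative_amounts(tc, cfg) # 1.5, 2.9
#' @export
corrected_cumulative_amounts <- function(tc, cfg) {
  stopifnot(inherits(tc, "transport_timecourse"),
            inherits(cfg, "transwell_config"))
  conc <- tc$basolateral_concentrations
  removed_before <- c(0, cumsum(conc)[-length(conc)])
  conc * cfg$basolateral_volume + cfg$sample_volume * removed_before
}

#' Appearance rate of compound in the receiver compartment
#'
#' Estimates the linear appearance rate dQ/dt (nmol/s) from the corrected
#' cumulative amounts. The default, `mode = "single_point"`, divides the
#' amount at `window_end` minutes by the elapsed time, matching the common
#' practice of reading the rate off a single time point inside the linear
#' phase. `mode = "ols"` instead fits a zero-intercept least-squares line
#' through all points with time <= `window_end` (slope =
#' sum(t Q) / sum(t^2)).
#'
#' @param amounts Cumulative amounts in nmol (e.g. from
#'   [corrected_cumulative_amounts()]).
#' @param times Sampling times in minutes, same length as `amounts`.
#' @param window_end End of the linear window in minutes; must be one of
#'   `times`. Default 30 min.
#' @param mode `"single_point"` (default) or `"ols"`.
#' @return Appearance rate in nmol/s.
#' @examples
#' estimate_appearance_rate(c(1.8, 3.6), c(15, 30)) # 0.002 nmol/s
#' @export
estimate_appearance_rate <- function(amounts, times, window_end = 30,
                                     mode = c("single_point", "ols")) {
  mode <- match.arg(mode)
  if (length(amounts) != length(times)) {
    stop("'amounts' and 'times' must have the same length", call. = FALSE)
  }
  if (!window_end %in% times) {
    stop(sprintf("window_end = %g is not a sampling time (available: %s)",
                 window_end, paste(times, collapse = ", ")), call. = FALSE)
  }
  if (mode == "single_point") {
    q <- amounts[match(window_end, times)]
    return(q / (window_end * 60))
  }
  keep <- times <= window_end
  t_s <- times[keep] * 60
  sum(t_s * amounts[keep]) / sum(t_s^2)
}

#' Apparent permeability coefficient
#'
#' Papp (cm/s) = (dQ/dt) / (A x C0), with the appearance rate in nmol/s,
#' membrane area A in cm^2 and initial donor concentration C0 in nmol/cm^3.
#' Since 1 ml = 1 cm^3, a concentration in uM (nmol/ml) is numerically
#' equal to nmol/cm^3, so the configured uM value is used directly.
#'
#' @param rate Appearance rate in nmol/s; must be >= 0.
#' @param cfg A [transwell_config()]; supplies A and C0.
#' @return Papp in cm/s.
#' @examples
#' cfg <- transwell_config(membrane_area = 1.12,
#'                         initial_apical_concentration = 50)
#' papp_coefficient(2.179e-3, cfg) # ~38.9e-6 cm/s
#' @export
papp_coefficient <- function(rate, cfg) {
  stopifnot(inherits(cfg, "transwell_config"))
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate < 0) {
    stop("'rate' must be a single non-negative number", call. = FALSE)
  }
  # C0 [uM] = C0 [nmol/ml] = C0 [nmol/cm^3] because 1 ml = 1 cm^3
  c0_nmol_per_cm3 <- cfg$initial_apical_concentration
  rate / (cfg$membrane_area * c0_nmol_per_cm3)
}

#' Papp relative to the reference compound
#'
#' Expresses a Papp coefficient as a fraction of the reference compound's
#' Papp (antipyrine in the placental-barrier application, a marker of free
#' transfer). Report tables conventionally round this to 2 decimals.
#'
#' @param papp Papp of the compound of interest, cm/s.
#' @param reference_papp Papp of the reference compound, cm/s; must be > 0.
#' @return Dimensionless fraction.
#' @examples
#' relative_papp(24.4e-6, 38.9e-6) # ~0.63
#' @export
relative_papp <- function(papp, reference_papp) {
  if (!is.numeric(reference_papp) || length(reference_papp) != 1L ||
      !is.finite(reference_papp) || reference_papp <= 0) {
    stop("'reference_papp' must be a single positive number", call. = FALSE)
  }
  papp / reference_papp
}

#' Mass balance of a transport experiment
#'
#' Percentage of the dosed amount recovered at the end of the experiment:
#' donor remainder + sampling-corrected cumulative receiver amount + amount
#' associated with the cell layer, relative to the initial amount. Values
#' outside `window` raise a QC flag (they are flagged, never dropped).
#'
#' @param tc A [transport_timecourse()] with terminal apical concentration
#'   and cell-associated amount present.
#' @param cfg A [transwell_config()].
#' @param window Acceptance window in percent, default `c(90, 110)`.
#' @return List with `percent` and `qc_flags` (character vector, empty when
#'   the balance is inside the window).
#' @examples
#' cfg <- transwell_config()
#' tc <- transport_timecourse("x", "r1", 30, 2.5, 35, 2.5)
#' mass_balance(tc, cfg)
#' @export
mass_balance <- function(tc, cfg, window = c(90, 110)) {
  stopifnot(inherits(tc, "transport_timecourse"),
            inherits(cfg, "transwell_config"))
  missing_fields <- character(0)
  if (!is.finite(tc$final_apical_concentration)) {
    missing_fields <- c(missing_fields, "final_apical_concentration")
  }
  if (!is.finite(tc$cell_associated_amount)) {
    missing_fields <- c(missing_fields, "cell_associated_amount")
  }
  if (length(missing_fields)) {
    stop("mass balance needs terminal measurements; missing: ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  apical <- tc$final_apical_concentration * cfg$apical_volume
  baso <- utils::tail(corrected_cumulative_amounts(tc, cfg), 1)
  pct <- 100 * (apical + baso + tc$cell_associated_amount) / cfg$initial_amount
  flags <- character(0)
  if (pct < window[1] || pct > window[2]) {
    flags <- sprintf("mass balance %.1f%% outside [%g, %g]%%",
                     pct, window[1], window[2])
  }
  list(percent = pct, qc_flags = flags)
}

#' Intracellular accumulation as percent of the dosed amount
#'
#' @param cell_amount Amount recovered from the cell layer, nmol (>= 0).
#' @param cfg A [transwell_config()].
#' @return Percent of the initial amount.
#' @examples
#' intracellular_accumulation_percent(5, transwell_config()) # 20
#' @export
intracellular_accumulation_percent <- function(cell_amount, cfg) {
  stopifnot(inherits(cfg, "transwell_config"))
  if (!is.numeric(cell_amount) || any(cell_amount < 0)) {
    stop("'cell_amount' must be non-negative", call. = FALSE)
  }
  100 * cell_amount / cfg$initial_amount
}

#' Per-compound transport summary
#'
#' Runs the full receiver-side analysis on a set of time courses and
#' summarises per compound: mean +/- SD Papp across replicates, relative
#' Papp against the reference compound, intracellular accumulation and mass
#' balance QC. Mirrors the conventional transport-report layout
#' (accumulation %, Papp x 1e-6 cm/s, relative Papp to 2 decimals).
#'
#' @param timecourses List of [transport_timecourse()] objects (several
#'   compounds, several replicates each).
#' @param cfg A [transwell_config()].
#' @param reference_compound Compound id used as the relative-Papp
#'   denominator.
#' @param window_end Linear-window end passed to
#'   [estimate_appearance_rate()].
#' @param rate_mode Rate mode passed to [estimate_appearance_rate()].
#' @param mass_balance_window QC window passed to [mass_balance()];
#'   balances are only computed where terminal measurements are present.
#' @return `data.frame` with one row per compound: `compound`,
#'   `accumulation_percent`, `papp_mean`, `papp_sd` (cm/s),
#'   `relative_papp`, `n_replicates`, `qc_flags` (collapsed text).
#' @export
summarize_transport <- function(timecourses, cfg,
                                reference_compound = "antipyrine",
                                window_end = 30,
                                rate_mode = c("single_point", "ols"),
                                mass_balance_window = c(90, 110)) {
  rate_mode <- match.arg(rate_mode)
  stopifnot(length(timecourses) > 0)
  compounds <- vapply(timecourses, function(tc) tc$compound_id, character(1))
  if (!reference_compound %in% compounds) {
    stop(sprintf("reference compound '%s' not present in transport data",
                 reference_compound), call. = FALSE)
  }
  per_insert <- lapply(timecourses, function(tc) {
    q <- corrected_cumulative_amounts(tc, cfg)
    rate <- estimate_appearance_rate(q, tc$sample_times, window_end,
                                     mode = rate_mode)
    papp <- papp_coefficient(rate, cfg)
    flags <- character(0)
    if (is.finite(tc$final_apical_concentration) &&
        is.finite(tc$cell_associated_amount)) {
      mb <- mass_balance(tc, cfg, mass_balance_window)
      flags <- mb$qc_flags
    }
    acc <- if (is.finite(tc$cell_associated_amount)) {
      intracellular_accumulation_percent(tc$cell_associated_amount, cfg)
    } else NA_real_
    data.frame(compound = tc$compound_id, papp = papp,
               accumulation = acc,
               qc = paste(flags, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  per_insert <- do.call(rbind, per_insert)
  agg <- lapply(split(per_insert, per_insert$compound), function(d) {
    data.frame(
      compound = d$compound[1],
      accumulation_percent = mean(d$accumulation),
      papp_mean = mean(d$papp),
      papp_sd = if (nrow(d) > 1) stats::sd(d$papp) else NA_real_,
      n_replicates = nrow(d),
      qc_flags = paste(d$qc[nzchar(d$qc)], collapse = "; "),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, agg)
  ref_papp <- out$papp_mean[out$compound == reference_compound]
  out$relative_papp <- relative_papp(out$papp_mean, ref_papp)
  rownames(out) <- NULL
  out[, c("compound", "accumulation_percent", "papp_mean", "papp_sd",
          "relative_papp", "n_replicates", "qc_flags")]
}
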