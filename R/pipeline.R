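# End-to-end orchestration: transport -> differentiation/viability ->
# benchmark-concentration modelling -> corrected potency ranking.

#' Default pipeline settings
#'
#' @return Named list of the tunables consumed by [run_pipeline()]:
#'   transwell geometry, reference compound, BMD settings and QC windows.
#' @export
default_pipeline_settings <- function() {
  list(
    transwell = list(membrane_area = 1.12, apical_volume = 0.5,
                     basolateral_volume = 1.5, sample_volume = 0.2,
                     initial_apical_concentration = 50),
    reference_compound = "antipyrine",
    rate_window_end = 30,
    rate_mode = "single_point",
    mass_balance_window = c(90, 110),
    bmr = 0.5,
    p_min = 0.1,
    residual_max = 2,
    multistage_degree = NULL,
    seed = 101,
    viability_threshold = 80
  )
}

# merge a (possibly nested) config read from file over the defaults
merge_settings <- function(settings, defaults = default_pipeline_settings()) {
  if (is.null(settings)) return(defaults)
  for (nm in names(settings)) {
    if (is.list(settings[[nm]]) && is.list(defaults[[nm]])) {
      defaults[[nm]] <- utils::modifyList(defaults[[nm]], settings[[nm]])
    } else {
      defaults[[nm]] <- settings[[nm]]
    }
  }
  defaults
}

#' Run the combined screening pipeline
#'
#' Executes the full analysis: (1) transwell kinetics to relative Papp;
#' (2) differentiation-run gating, pooling and benchmark-concentration
#' modelling per compound; (3) cytotoxicity guard at the selected BMC;
#' (4) transfer-corrected potency ranking and concordance with an external
#' (in vivo) ordering. Any stage may be skipped by passing precomputed
#' inputs (e.g. `relative_papp` instead of `timecourses`).
#'
#' @param timecourses List of [transport_timecourse()] objects (all
#'   compounds), or `NULL` when `relative_papp` is supplied directly.
#' @param runs Named list (by compound) of lists of
#'   [differentiation_run()] objects.
#' @param curves List of [viability_curve()] objects (optional; enables
#'   the cytotoxicity guard).
#' @param in_vivo_order Character vector of compound ids, most toxic
#'   first (optional; enables the ranking comparison).
#' @param relative_papp Optional named numeric vector of precomputed
#'   relative Papp values (replaces the transport stage).
#' @param settings Named list as from [default_pipeline_settings()];
#'   partial lists are merged over the defaults.
#' @return List with `transport_summary`, `bmc_estimates` (per compound),
#'   `summaries` (combined table), `ranking`, `concordance`,
#'   `guard_verdicts` and `provenance`.
#' @export
run_pipeline <- function(timecourses = NULL, runs, curves = NULL,
                         in_vivo_order = NULL, relative_papp = NULL,
                         settings = NULL) {
  cfgset <- merge_settings(settings)
  transport_summary <- NULL
  if (is.null(relative_papp)) {
    if (is.null(timecourses)) {
      stop("either 'timecourses' or 'relative_papp' must be supplied",
           call. = FALSE)
    }
    cfg <- do.call(transwell_config, cfgset$transwell)
    transport_summary <- summarize_transport(
      timecourses, cfg,
      reference_compound = cfgset$reference_compound,
      window_end = cfgset$rate_window_end,
      rate_mode = cfgset$rate_mode,
      mass_balance_window = cfgset$mass_balance_window)
    relative_papp <- stats::setNames(transport_summary$relative_papp,
                                     transport_summary$compound)
  }
  # differentiation + BMD per compound
  bmc_estimates <- lapply(names(runs), function(cid) {
    qd <- to_quantal(runs[[cid]])
    bmc_d50(qd, bmr = cfgset$bmr, p_min = cfgset$p_min,
            residual_max = cfgset$residual_max,
            multistage_degree = cfgset$multistage_degree,
            seed = cfgset$seed)
  })
  names(bmc_estimates) <- names(runs)
  bmcs <- vapply(bmc_estimates, `[[`, numeric(1), "bmc")
  # cytotoxicity guard
  guard_verdicts <- NULL
  if (!is.null(curves)) {
    curve_ids <- vapply(curves, `[[`, character(1), "compound_id")
    guard_verdicts <- lapply(names(bmcs), function(cid) {
      cc <- curves[curve_ids == cid]
      if (!length(cc)) return(NULL)
      cytotoxicity_guard(bmcs[[cid]], cc,
                         threshold = cfgset$viability_threshold)
    })
    names(guard_verdicts) <- names(bmcs)
  }
  # combine and rank
  missing_papp <- setdiff(names(bmcs), names(relative_papp))
  if (length(missing_papp)) {
    stop("no relative Papp for compound(s): ",
         paste(missing_papp, collapse = ", "), call. = FALSE)
  }
  summaries <- compound_summary(names(bmcs), unname(bmcs),
                                unname(relative_papp[names(bmcs)]),
                                in_vivo_order = in_vivo_order)
  ranking <- concordance <- NULL
  if (!is.null(in_vivo_order)) {
    ranking <- ranking_table(summaries)
    corrected_order <- potency_ranking(summaries$compound,
                                       summaries$corrected_bmc_d50)
    uncorrected_order <- potency_ranking(summaries$compound,
                                         summaries$bmc_d50)
    concordance <- list(
      corrected_vs_in_vivo = rank_concordance(corrected_order,
                                              in_vivo_order),
      uncorrected_vs_in_vivo = rank_concordance(uncorrected_order,
                                                in_vivo_order)
    )
  }
  list(
    transport_summary = transport_summary,
    bmc_estimates = bmc_estimates,
    summaries = summaries,
    ranking = ranking,
    concordance = concordance,
    guard_verdicts = guard_verdicts,
    provenance = list(settings = cfgset,
                      timestamp = format(Sys.time(), tz = "UTC"),
                      package_version =
                        as.character(utils::packageVersion("devtoxrank")))
  )
}

#' Report-style transport table
#'
#' Rounds a [summarize_transport()] result to reporting precision: Papp
#' as `x 1e-6 cm/s` to 1 decimal, relative Papp to 2 decimals,
#' accumulation to whole percent.
#'
#' @param transport_summary Output of [summarize_transport()].
#' @return `data.frame` ready to print/write.
#' @export
format_transport_table <- function(transport_summary) {
  data.frame(
    compound = transport_summary$compound,
    accumulation_percent = round(transport_summary$accumulation_percent),
    papp_1e6_cm_s = round(transport_summary$papp_mean * 1e6, 1),
    papp_sd_1e6_cm_s = round(transport_summary$papp_sd * 1e6, 1),
    relative_papp = round(transport_summary$relative_papp, 2),
    stringsAsFactors = FALSE
  )
}

#' Report-style potency table
#'
#' Rounds BMC50 and corrected BMC50 to 1 decimal (uM), the reporting
#' precision of the combined approach.
#'
#' @param summaries Output of [compound_summary()].
#' @return `data.frame` ready to print/write.
#' @export
format_potency_table <- function(summaries) {
  out <- summaries
  out$bmc_d50 <- round(out$bmc_d50, 1)
  out$corrected_bmc_d50 <- round(out$corrected_bmc_d50, 1)
  out
}
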