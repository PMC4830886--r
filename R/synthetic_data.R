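# Seeded generators emulating both assays with known ground truth.

#' Simulate a transwell transport time course
#'
#' Forward-simulates apical-to-basolateral transfer with flux
#' `J = Papp x A x C_apical` by explicit time stepping (forward Euler,
#' dt = 0.1 min), including apical depletion — so the downstream linear-
#' phase analysis is genuinely tested against curvature rather than having
#' linearity baked in. At each scheduled sampling time the configured
#' sample volume is withdrawn from the receiver and replaced with blank
#' buffer, exactly as in the wet protocol, so the sampling correction in
#' the analysis is exercised. Optional constant-rate cell sequestration
#' draws a chosen fraction of the dosed amount out of the donor
#' compartment over the run. Measurement noise is multiplicative lognormal
#' (keeps concentrations positive) with the given coefficient of
#' variation.
#'
#' @param true_papp True permeability in cm/s.
#' @param cfg A [transwell_config()].
#' @param sample_times Sampling schedule in minutes (default the standard
#'   15/30/60/90).
#' @param cv Coefficient of variation of the lognormal measurement noise
#'   (0 = noiseless).
#' @param cell_uptake_fraction Fraction of the dosed amount sequestered by
#'   the cell layer over the run, in `[0, 1)`.
#' @param seed Integer seed; identical seeds give identical output.
#' @param compound_id,replicate_id Identifiers for the output object.
#' @param dt Euler step in minutes (default 0.1).
#' @return A [transport_timecourse()] whose measured values derive from
#'   the simulated truth.
#' @examples
#' cfg <- transwell_config()
#' simulate_transport_timecourse(38.9e-6, cfg, seed = 1)
#' @export
simulate_transport_timecourse <- function(true_papp, cfg,
                                          sample_times = c(15, 30, 60, 90),
                                          cv = 0,
                                          cell_uptake_fraction = 0,
                                          seed = 1,
                                          compound_id = "synthetic",
                                          replicate_id = "r1",
                                          dt = 0.1) {
  stopifnot(inherits(cfg, "transwell_config"))
  if (length(sample_times) < 1) stop("empty sampling schedule", call. = FALSE)
  if (any(diff(sample_times) <= 0) || any(sample_times <= 0)) {
    stop("'sample_times' must be positive and strictly increasing",
         call. = FALSE)
  }
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (cell_uptake_fraction < 0 || cell_uptake_fraction >= 1) {
    stop("cell_uptake_fraction must be in [0, 1)", call. = FALSE)
  }
  with_local_seed(seed, {
    q_apical <- cfg$initial_amount      # nmol
    q_baso <- 0
    q_cell <- 0
    t_end <- max(sample_times)
    uptake_rate <- cell_uptake_fraction * cfg$initial_amount / t_end # nmol/min
    measured <- numeric(length(sample_times))
    next_sample <- 1L
    t <- 0
    n_steps <- round(t_end / dt)
    sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
    for (step in seq_len(n_steps)) {
      c_apical <- q_apical / cfg$apical_volume              # nmol/ml = uM
      flux <- true_papp * cfg$membrane_area * c_apical * 60 # nmol/min
      transfer <- min(flux * dt, q_apical)
      q_apical <- q_apical - transfer
      q_baso <- q_baso + transfer
      if (uptake_rate > 0) {
        taken <- min(uptake_rate * dt, q_apical)
        q_apical <- q_apical - taken
        q_cell <- q_cell + taken
      }
      t <- t + dt
      while (next_sample <= length(sample_times) &&
             t >= sample_times[next_sample] - dt / 2) {
        c_true <- q_baso / cfg$basolateral_volume
        noise <- if (sdlog > 0) {
          stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
        } else 1
        measured[next_sample] <- c_true * noise
        # withdraw the aliquot, replace with blank buffer (volume constant)
        q_baso <- q_baso - c_true * cfg$sample_volume
        next_sample <- next_sample + 1L
      }
    }
    c_apical_final <- q_apical / cfg$apical_volume
    noise_a <- if (sdlog > 0) {
      stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else 1
    transport_timecourse(compound_id, replicate_id, sample_times, measured,
                         final_apical_concentration = c_apical_final * noise_a,
                         cell_associated_amount = q_cell)
  })
}

#' Simulate a set of differentiation runs
#'
#' Draws contracting-well counts per concentration as
#' `Binomial(wells, 1 - p_affected(d))` under a chosen generating quantal
#' model; the solvent control is drawn with its own contracting
#' probability (default 0.97, comfortably above the 21/24 gate in
#' expectation).
#'
#' @param spec A [dr_model_spec()] for the generating model.
#' @param params Named generating parameters for `spec`.
#' @param concentrations Non-zero test concentrations in uM (default a
#'   grid spanning the standard 0.2-60 uM test range).
#' @param wells Wells per concentration (default 24).
#' @param experiments Number of independent runs (default 3).
#' @param control_p_contracting Probability a control well contracts.
#' @param seed Integer seed.
#' @param compound_id Identifier for the output runs.
#' @return List of [differentiation_run()] objects, one per experiment.
#' @examples
#' sp <- dr_model_spec("quantal_linear")
#' runs <- simulate_differentiation_assay(sp, c(g = 0.02, b = 0.165),
#'                                        seed = 7)
#' @export
simulate_differentiation_assay <- function(spec, params,
                                           concentrations =
                                             c(0.2, 1, 3, 10, 30, 60),
                                           wells = 24, experiments = 3,
                                           control_p_contracting = 0.97,
                                           seed = 1,
                                           compound_id = "synthetic") {
  stopifnot(inherits(spec, "dr_model_spec"))
  if (any(concentrations <= 0)) {
    stop("'concentrations' are the non-zero groups; the control is added ",
         "automatically", call. = FALSE)
  }
  p_aff <- model_response(spec, params, concentrations)
  with_local_seed(seed, {
    lapply(seq_len(experiments), function(e) {
      ctrl <- stats::rbinom(1, wells, control_p_contracting)
      contracting <- stats::rbinom(length(concentrations), wells, 1 - p_aff)
      differentiation_run(compound_id, paste0("exp", e),
                          c(0, concentrations), wells,
                          c(ctrl, contracting))
    })
  })
}

#' Simulate a viability curve
#'
#' Four-parameter-logistic mean plus Gaussian noise, floored at 0.
#'
#' @param bottom,top,ec50,hill 4PL parameters (percent scale; `top` is
#'   typically 100).
#' @param concentrations Concentration grid in uM.
#' @param noise_sd SD of the additive Gaussian noise (percent points).
#' @param exposure_days Exposure label (1 or 5).
#' @param seed Integer seed.
#' @param compound_id Identifier.
#' @return A [viability_curve()].
#' @export
simulate_viability <- function(bottom, top, ec50, hill,
                               concentrations = c(0.2, 1, 3, 10, 30, 60),
                               noise_sd = 0, exposure_days = 5, seed = 1,
                               compound_id = "synthetic") {
  mu <- bottom + (top - bottom) / (1 + (concentrations / ec50)^hill)
  with_local_seed(seed, {
    obs <- pmax(mu + stats::rnorm(length(mu), 0, noise_sd), 0)
    viability_curve(compound_id, exposure_days, concentrations, obs)
  })
}

#' Simulate a full multi-compound cohort
#'
#' Generates, for each row of `truth`, transwell time courses (replicated)
#' and differentiation runs from known true Papp and true BMC50, so the
#' end-to-end pipeline's ranking can be compared with the known ordering.
#' Differentiation responses follow a quantal-linear model with slope
#' `log(2) / bmc50` (extra risk 0.5 at the true BMC by construction).
#' Default truth values span the ranges typical of the six-triazole case
#' study (Papp 3-39 x 1e-6 cm/s, BMC 1.8-11.4 uM) plus the reference
#' compound.
#'
#' @param truth `data.frame` with columns `compound`, `papp` (cm/s),
#'   `bmc50` (uM; NA for transport-only reference compounds).
#' @param cfg A [transwell_config()].
#' @param n_replicates Transwell replicates per compound.
#' @param cv Transport measurement noise CV.
#' @param seed Integer seed.
#' @param ... Passed to [simulate_differentiation_assay()].
#' @return List with `timecourses` (flat list) and `runs` (list per
#'   compound with a BMC truth).
#' @export
simulate_cohort <- function(truth = default_cohort_truth(),
                            cfg = transwell_config(),
                            n_replicates = 3, cv = 0.05, seed = 1, ...) {
  tcs <- list()
  runs <- list()
  for (i in seq_len(nrow(truth))) {
    cid <- truth$compound[i]
    for (r in seq_len(n_replicates)) {
      tcs[[length(tcs) + 1L]] <- simulate_transport_timecourse(
        truth$papp[i], cfg, cv = cv,
        cell_uptake_fraction = 0.05,
        seed = seed + 1000L * i + r,
        compound_id = cid, replicate_id = paste0("r", r))
    }
    if (is.finite(truth$bmc50[i])) {
      runs[[cid]] <- simulate_differentiation_assay(
        dr_model_spec("quantal_linear"),
        c(g = 0.02, b = log(2) / truth$bmc50[i]),
        seed = seed + 97L * i, compound_id = cid, ...)
    }
  }
  list(timecourses = tcs, runs = runs)
}

#' Default ground truth for the synthetic cohort
#'
#' Six test compounds spanning the case-study parameter ranges plus the
#' freely transported reference compound (no differentiation endpoint).
#' @return `data.frame` with `compound`, `papp`, `bmc50`.
#' @export
default_cohort_truth <- function() {
  data.frame(
    compound = c("cmpA", "cmpB", "cmpC", "cmpD", "cmpE", "cmpF",
                 "reference"),
    papp = c(11.5e-6, 3.0e-6, 24.4e-6, 18.4e-6, 7.9e-6, 7.1e-6, 38.9e-6),
    bmc50 = c(6.9, 11.0, 11.4, 1.8, 4.2, 4.3, NA),
    stringsAsFactors = FALSE
  )
}
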