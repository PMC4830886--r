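#' Transwell geometry and dosing configuration
#'
#' Bundles the physical constants of a transwell transport experiment:
#' membrane area, compartment volumes, the volume withdrawn (and replaced
#' with blank buffer) at each sampling time, and the initial apical donor
#' concentration. Defaults describe a 12-mm insert dosed at 50 uM.
#'
#' @param membrane_area Membrane (cell layer) area in cm^2. The default
#'   1.12 cm^2 is the standard vendor growth area of a 12-mm insert.
#' @param apical_volume Apical (donor) compartment volume in ml.
#' @param basolateral_volume Basolateral (receiver) compartment volume in ml.
#' @param sample_volume Volume in ml withdrawn from the receiver at each
#'   sampling time and replaced by blank transport buffer.
#' @param initial_apical_concentration Donor concentration at t = 0 in uM.
#'
#' @return An object of class `transwell_config`: a list with the five
#'   arguments plus `initial_amount`, the dosed amount in nmol
#'   (concentration x apical volume; 1 uM x 1 ml = 1 nmol).
#' @examples
#' cfg <- transwell_config()
#' cfg$initial_amount # 25 nmol
#' @export
transwell_config <- function(membrane_area = 1.12,
                             apical_volume = 0.5,
                             basolateral_volume = 1.5,
                             sample_volume = 0.2,
                             initial_apical_concentration = 50) {
  for (nm in c("membrane_area", "apical_volume", "basolateral_volume",
               "sample_volume", "initial_apical_concentration")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("'%s' must be a single positive number", nm), call. = FALSE)
    }
  }
  if (sample_volume >= basolateral_volume) {
    stop("'sample_volume' must be smaller than 'basolateral_volume'",
         call. = FALSE)
  }
  structure(
    list(
      membrane_area = membrane_area,
      apical_volume = apical_volume,
      basolateral_volume = basolateral_volume,
      sample_volume = sample_volume,
      initial_apical_concentration = initial_apical_concentration,
      initial_amount = initial_apical_concentration * apical_volume
    ),
    class = "transwell_config"
  )
}

#' @export
print.transwell_config <- function(x, ...) {
  cat("Transwell configuration\n")
  cat(sprintf("  membrane area        : %.3g cm^2\n", x$membrane_area))
  cat(sprintf("  apical volume        : %.3g ml\n", x$apical_volume))
  cat(sprintf("  basolateral volume   : %.3g ml\n", x$basolateral_volume))
  cat(sprintf("  sample volume        : %.3g ml\n", x$sample_volume))
  cat(sprintf("  initial concentration: %.3g uM (%.3g nmol)\n",
              x$initial_apical_concentration, x$initial_amount))
  invisible(x)
}

#' Single-insert transport time course
#'
#' Container for the measurements taken on one transwell insert: receiver
#' (basolateral) concentrations at each sampling time, plus the terminal
#' donor concentration and the amount recovered from the cell layer, both
#' needed for the mass balance.
#'
#' @param compound_id Compound identifier.
#' @param replicate_id Insert/replicate identifier.
#' @param sample_times Sampling times in minutes, strictly increasing.
#' @param basolateral_concentrations Measured receiver concentrations in uM,
#'   one per sampling time, as sampled (i.e. after all earlier withdrawals
#'   and buffer replacements).
#' @param final_apical_concentration Donor concentration in uM at the end of
#'   the experiment (`NA` if not measured).
#' @param cell_associated_amount Amount in nmol recovered from the cell
#'   layer at the end of the experiment (`NA` if not measured).
#'
#' @return An object of class `transport_timecourse`.
#' @examples
#' transport_timecourse("antipyrine", "r1", c(15, 30, 60, 90),
#'                      c(1.2, 2.4, 4.6, 6.5), 35.2, 0.1)
#' @export
transport_timecourse <- function(compound_id, replicate_id,
                                 sample_times, basolateral_concentrations,
                                 final_apical_concentration = NA_real_,
                                 cell_associated_amount = NA_real_) {
  if (length(sample_times) < 1L) {
    stop("at least one sampling time is required", call. = FALSE)
  }
  if (length(sample_times) != length(basolateral_concentrations)) {
    stop("'sample_times' and 'basolateral_concentrations' lengths differ",
         call. = FALSE)
  }
  if (any(diff(sample_times) <= 0)) {
    stop("'sample_times' must be strictly increasing", call. = FALSE)
  }
  if (any(sample_times <= 0)) {
    stop("'sample_times' must be positive", call. = FALSE)
  }
  if (any(basolateral_concentrations < 0)) {
    stop("negative basolateral concentration", call. = FALSE)
  }
  structure(
    list(
      compound_id = as.character(compound_id),
      replicate_id = as.character(replicate_id),
      sample_times = as.numeric(sample_times),
      basolateral_concentrations = as.numeric(basolateral_concentrations),
      final_apical_concentration = as.numeric(final_apical_concentration),
      cell_associated_amount = as.numeric(cell_associated_amount)
    ),
    class = "transport_timecourse"
  )
}

#' @export
print.transport_timecourse <- function(x, ...) {
  cat(sprintf("Transport time course: %s (replicate %s)\n",
              x$compound_id, x$replicate_id))
  print(data.frame(time_min = x$sample_times,
                   basolateral_uM = x$basolateral_concentrations))
  invisible(x)
}
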