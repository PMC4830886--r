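cfg <- transwell_config()

test_that("same seed gives identical synthetic output", {
  a <- simulate_transport_timecourse(1e-5, cfg, cv = 0.1, seed = 5)
  b <- simulate_transport_timecourse(1e-5, cfg, cv = 0.1, seed = 5)
  expect_identical(a, b)
  c_ <- simulate_transport_timecourse(1e-5, cfg, cv = 0.1, seed = 6)
  expect_false(identical(a$basolateral_concentrations,
                         c_$basolateral_concentrations))
  r1 <- simulate_differentiation_assay(dr_model_spec("quantal_linear"),
                                       c(g = 0.02, b = 0.1), seed = 5)
  r2 <- simulate_differentiation_assay(dr_model_spec("quantal_linear"),
                                       c(g = 0.02, b = 0.1), seed = 5)
  expect_identical(r1, r2)
  v1 <- simulate_viability(10, 100, 20, 2, noise_sd = 5, seed = 5)
  v2 <- simulate_viability(10, 100, 20, 2, noise_sd = 5, seed = 5)
  expect_identical(v1, v2)
})

test_that("zero permeability transports nothing; mass is conserved", {
  tc0 <- simulate_transport_timecourse(0, cfg, seed = 1)
  expect_equal(tc0$basolateral_concentrations, rep(0, 4))
  tc <- simulate_transport_timecourse(2e-5, cfg, cv = 0,
                                      cell_uptake_fraction = 0.1, seed = 1)
  mb <- mass_balance(tc, cfg)
  expect_equal(mb$percent, 100, tolerance = 0.5)
  expect_gt(tc$cell_associated_amount, 0)
  expect_equal(intracellular_accumulation_percent(tc$cell_associated_amount,
                                                  cfg),
               10, tolerance = 0.5)
})

test_that("noiseless transport is recovered by the analysis within the
           linear-phase bias budget", {
  # mid-range permeability: donor depletion over the 30-min window is small
  recover <- function(papp) {
    tc <- simulate_transport_timecourse(papp, cfg, cv = 0, seed = 2)
    q <- corrected_cumulative_amounts(tc, cfg)
    papp_coefficient(estimate_appearance_rate(q, tc$sample_times, 30), cfg)
  }
  expect_lt(abs(recover(7.9e-6) - 7.9e-6) / 7.9e-6, 0.02)
  expect_lt(abs(recover(3.0e-6) - 3.0e-6) / 3.0e-6, 0.01)
  # at the reference compound's high permeability the single-point read
  # under-estimates by the donor-depletion factor (1 - exp(-kt))/kt
  papp_hi <- 38.9e-6
  k <- papp_hi * cfg$membrane_area / cfg$apical_volume * 60 # per min
  expected_bias <- (1 - exp(-k * 30)) / (k * 30) - 1
  est <- recover(papp_hi)
  expect_equal(est / papp_hi - 1, expected_bias, tolerance = 0.01)
})

test_that("differentiation generator matches its binomial design", {
  # flat zero response: every run fully contracting and accepted
  runs0 <- simulate_differentiation_assay(
    dr_model_spec("quantal_linear"), c(g = 0, b = 1e-8),
    control_p_contracting = 1, seed = 4)
  for (r in runs0) {
    expect_true(all(r$wells_contracting == 24))
    expect_true(accept_differentiation_run(r)$accepted)
  }
  # control probability 0.8: rejection rate matches the exact binomial tail
  p_ctrl <- 0.8
  expected_reject <- pbinom(20, 24, p_ctrl)
  n_sim <- 2000
  runs <- simulate_differentiation_assay(
    dr_model_spec("quantal_linear"), c(g = 0.02, b = 0.05),
    experiments = n_sim, control_p_contracting = p_ctrl, seed = 8)
  rejected <- sum(!vapply(runs, function(r) {
    accept_differentiation_run(r)$accepted
  }, logical(1)))
  mc_err <- 3 * sqrt(expected_reject * (1 - expected_reject) / n_sim)
  expect_lt(abs(rejected / n_sim - expected_reject), mc_err)
})

test_that("viability generator round-trips through the 4PL fit", {
  v <- simulate_viability(5, 100, 15, 2,
                          concentrations = c(0.5, 1, 3, 10, 30, 60),
                          noise_sd = 0, seed = 1)
  expect_true(v$fit$converged)
  expect_equal(v$fit$ec50, 15, tolerance = 1e-6)
  expect_equal(v$fit$hill, 2, tolerance = 1e-5)
  flat <- simulate_viability(60, 60, 15, 2, noise_sd = 0, seed = 1)
  expect_false(flat$fit$converged)
})

test_that("known potency ordering is recovered end to end across seeds", {
  # cohort with geometrically separated corrected BMCs so the ordering is
  # identifiable at 3 x 24 wells per concentration
  truth <- data.frame(
    compound = c("c1", "c2", "c3", "c4", "c5"),
    papp = c(29.2e-6, 23.3e-6, 19.5e-6, 11.7e-6, 5.8e-6),
    bmc50 = c(1.5, 3, 6.25, 9.3, 11.7)
  )
  truth$corrected <- truth$bmc50 / (truth$papp / 38.9e-6)
  true_order <- truth$compound[order(truth$corrected)]
  truth <- rbind(truth[, 1:3],
                 data.frame(compound = "reference", papp = 38.9e-6,
                            bmc50 = NA))
  n_rep <- 20
  hits <- 0
  for (rep in seq_len(n_rep)) {
    coh <- simulate_cohort(truth, cfg, cv = 0.05, seed = 1000 + rep)
    res <- suppressWarnings(run_pipeline(
      timecourses = coh$timecourses, runs = coh$runs,
      settings = list(reference_compound = "reference")))
    got <- potency_ranking(res$summaries$compound,
                           res$summaries$corrected_bmc_d50)
    if (identical(as.character(got), true_order)) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})
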