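cfg <- transwell_config()

test_that("sampling correction reproduces hand-computed cumulative amounts", {
  one <- transport_timecourse("x", "r", 15, 1.0)
  expect_equal(corrected_cumulative_amounts(one, cfg), 1.5)

  two <- transport_timecourse("x", "r", c(15, 30), c(1.0, 1.8))
  expect_equal(corrected_cumulative_amounts(two, cfg), c(1.5, 2.9))

  flat <- transport_timecourse("x", "r", c(15, 30, 45), c(2, 2, 2))
  expect_equal(corrected_cumulative_amounts(flat, cfg), c(3.0, 3.4, 3.8))
})

test_that("sampling correction equals event-by-event bookkeeping on random schedules", {
  set.seed(42)
  for (i in 1:100) {
    k <- sample(2:8, 1)
    amounts_in <- runif(k, 0, 2)
    vb <- runif(1, 1, 3)
    vs <- runif(1, 0.05, vb / 2)
    oracle <- event_bookkeeping(amounts_in, vb, vs)
    cfg_i <- transwell_config(basolateral_volume = vb, sample_volume = vs)
    tc <- transport_timecourse("x", "r", cumsum(runif(k, 5, 20)),
                               oracle$measured)
    expect_equal(corrected_cumulative_amounts(tc, cfg_i),
                 oracle$true_cumulative, tolerance = 1e-10)
  }
})

test_that("time course and config constructors validate their invariants", {
  expect_error(transport_timecourse("x", "r", c(15, 30), c(1, -1)),
               "negative")
  expect_error(transport_timecourse("x", "r", numeric(0), numeric(0)),
               "at least one")
  expect_error(transport_timecourse("x", "r", c(30, 15), c(1, 2)),
               "increasing")
  expect_error(transwell_config(sample_volume = 2), "smaller")
  expect_error(transwell_config(membrane_area = 0), "positive")
})

test_that("appearance rate: single-point read, OLS slope and exact line", {
  expect_equal(estimate_appearance_rate(c(1.8, 3.6), c(15, 30), 30),
               3.6 / 1800)
  # perfectly linear amounts: both modes recover the true rate
  r <- 0.002 # nmol/s
  times <- c(15, 30, 60, 90)
  q <- r * times * 60
  expect_equal(estimate_appearance_rate(q, times, 60), r)
  expect_equal(estimate_appearance_rate(q, times, 60, mode = "ols"), r)
  # zero-intercept least-squares closed form
  q2 <- c(1.5, 2.9)
  t2 <- c(15, 30)
  expect_equal(estimate_appearance_rate(q2, t2, 30, mode = "ols"),
               sum(t2 * 60 * q2) / sum((t2 * 60)^2))
  expect_error(estimate_appearance_rate(q2, t2, 45), "45")
})

test_that("Papp formula: units, homogeneity, zero and error cases", {
  expect_equal(papp_coefficient(0, cfg), 0)
  # dimensional hand calculation: nmol/s / (cm^2 x nmol/cm^3) = cm/s
  expect_equal(papp_coefficient(2.179e-3, cfg), 2.179e-3 / (1.12 * 50),
               tolerance = 1e-12)
  expect_equal(papp_coefficient(2.179e-3, cfg) * 1e6, 38.9, tolerance = 1e-3)
  # doubling C0 at fixed rate halves Papp
  cfg2 <- transwell_config(initial_apical_concentration = 100)
  expect_equal(papp_coefficient(1e-3, cfg2), papp_coefficient(1e-3, cfg) / 2)
  # invariance to joint rescaling of concentrations and C0
  tc <- transport_timecourse("x", "r", c(15, 30), c(1.0, 1.8))
  tc_scaled <- transport_timecourse("x", "r", c(15, 30), 3 * c(1.0, 1.8))
  cfg3 <- transwell_config(initial_apical_concentration = 3 * 50)
  rate1 <- estimate_appearance_rate(corrected_cumulative_amounts(tc, cfg),
                                    c(15, 30), 30)
  rate3 <- estimate_appearance_rate(corrected_cumulative_amounts(tc_scaled, cfg3),
                                    c(15, 30), 30)
  expect_equal(papp_coefficient(rate1, cfg), papp_coefficient(rate3, cfg3))
})

test_that("relative Papp reproduces reported fractions and the identity", {
  expect_equal(round(relative_papp(24.4e-6, 38.9e-6), 2), 0.63)
  expect_equal(round(relative_papp(11.5e-6, 38.9e-6), 2), 0.30)
  expect_identical(relative_papp(38.9e-6, 38.9e-6), 1)
  expect_error(relative_papp(1e-6, 0), "positive")
})

test_that("mass balance sums compartments and flags out-of-window values", {
  # all 25 nmol still apical: conservation gives exactly 100 %
  tc_full <- transport_timecourse("x", "r", 15, 0,
                                  final_apical_concentration = 50,
                                  cell_associated_amount = 0)
  expect_equal(mass_balance(tc_full, cfg)$percent, 100)
  # hand sum: 17.5 apical + 3.75 basolateral + 2.5 cells of 25 added
  tc <- transport_timecourse("x", "r", 15, 2.5,
                             final_apical_concentration = 35,
                             cell_associated_amount = 2.5)
  mb <- mass_balance(tc, cfg)
  expect_equal(mb$percent, 95)
  expect_length(mb$qc_flags, 0)
  # 85 % with window [90, 110] raises a flag
  tc_low <- transport_timecourse("x", "r", 15, 2.5,
                                 final_apical_concentration = 30,
                                 cell_associated_amount = 2.5)
  mb_low <- mass_balance(tc_low, cfg)
  expect_equal(mb_low$percent, 85)
  expect_match(mb_low$qc_flags, "outside")
  # missing terminal measurements named in the error
  tc_na <- transport_timecourse("x", "r", 15, 2.5)
  expect_error(mass_balance(tc_na, cfg), "final_apical_concentration")
})

test_that("intracellular accumulation is percent of the dosed amount", {
  expect_equal(intracellular_accumulation_percent(0, cfg), 0)
  expect_equal(intracellular_accumulation_percent(5, cfg), 20)
  expect_equal(intracellular_accumulation_percent(19.75, cfg), 79)
  expect_error(intracellular_accumulation_percent(-1, cfg), "non-negative")
})

test_that("transport summary aggregates replicates and keys on the reference", {
  tcs <- list(
    transport_timecourse("ref", "r1", c(15, 30), c(2.0, 3.8)),
    transport_timecourse("ref", "r2", c(15, 30), c(2.2, 4.0)),
    transport_timecourse("slow", "r1", c(15, 30), c(0.5, 1.0))
  )
  out <- summarize_transport(tcs, cfg, reference_compound = "ref")
  expect_setequal(out$compound, c("ref", "slow"))
  expect_equal(out$relative_papp[out$compound == "ref"], 1)
  expect_equal(out$n_replicates[out$compound == "ref"], 2)
  expect_lt(out$relative_papp[out$compound == "slow"], 1)
  expect_error(summarize_transport(tcs, cfg, reference_compound = "absent"),
               "absent")
})
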