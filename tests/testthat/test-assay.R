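test_that("control gate accepts at 21/24, rejects below, and is monotone", {
  run_with <- function(ctrl) {
    differentiation_run("x", "e1", c(0, 10), 24, c(ctrl, 5))
  }
  expect_true(accept_differentiation_run(run_with(21))$accepted)
  expect_true(accept_differentiation_run(run_with(24))$accepted)
  expect_false(accept_differentiation_run(run_with(20))$accepted)
  # monotone: increasing the control count never flips accepted -> rejected
  verdicts <- vapply(0:24, function(k) {
    accept_differentiation_run(run_with(k))$accepted
  }, logical(1))
  expect_true(all(diff(verdicts) >= 0))
  # proportional rule for other plate sizes: ceil(21/24 x wells)
  run48 <- differentiation_run("x", "e1", c(0, 10), 48, c(42, 5))
  expect_true(accept_differentiation_run(run48)$accepted)
  run48b <- differentiation_run("x", "e1", c(0, 10), 48, c(41, 5))
  expect_false(accept_differentiation_run(run48b)$accepted)
})

test_that("pooling preserves well counts and recodes affected as non-contracting", {
  r1 <- differentiation_run("x", "e1", c(0, 10), 24, c(22, 6))
  qd <- to_quantal(list(r1))
  expect_equal(qd$affected[qd$concentration == 10], 18)
  # three runs pooled: (22+21+23 contracting of 24 each) -> 6 affected of 72
  runs <- list(
    differentiation_run("x", "e1", c(0, 5), 24, c(24, 22)),
    differentiation_run("x", "e2", c(0, 5), 24, c(23, 21)),
    differentiation_run("x", "e3", c(0, 5), 24, c(22, 23))
  )
  qd3 <- to_quantal(runs)
  expect_equal(qd3$n[qd3$concentration == 5], 72)
  expect_equal(qd3$affected[qd3$concentration == 5], 6)
  # affected + contracting = wells at every group (round trip)
  expect_equal(qd3$n - qd3$affected,
               c(24 + 23 + 22, 22 + 21 + 23))
  # rejected runs are excluded with a message
  bad <- differentiation_run("x", "e4", c(0, 5), 24, c(19, 20))
  expect_message(qd4 <- to_quantal(c(runs, list(bad))), "e4")
  expect_equal(qd4$n[qd4$concentration == 5], 72)
  # mixed compounds refuse to pool
  other <- differentiation_run("y", "e1", c(0, 5), 24, c(23, 20))
  expect_error(to_quantal(list(r1, other)), "mix")
})

test_that("viability normalisation is linear and scale invariant", {
  expect_equal(normalize_viability(1, 1), 100)
  expect_equal(normalize_viability(0.1, 1.0), 10)
  a <- c(0.9, 0.5, 0.2)
  expect_equal(normalize_viability(a, 0.8),
               normalize_viability(a * 7, 0.8 * 7))
  expect_error(normalize_viability(a, 0), "positive")
})

test_that("4PL fit recovers noiseless parameters and flags degenerate data", {
  d <- c(0.5, 1, 3, 10, 30, 60)
  truth <- list(bottom = 8, top = 100, ec50 = 12, hill = 1.8)
  r <- truth$bottom + (truth$top - truth$bottom) /
    (1 + (d / truth$ec50)^truth$hill)
  fit <- fit_4pl(d, r)
  expect_true(fit$converged)
  expect_equal(fit$bottom, truth$bottom, tolerance = 1e-6)
  expect_equal(fit$top, truth$top, tolerance = 1e-6)
  expect_equal(fit$ec50, truth$ec50, tolerance = 1e-6)
  expect_equal(fit$hill, truth$hill, tolerance = 1e-6)
  # flat response is unidentifiable
  flat <- fit_4pl(d, rep(50, 6))
  expect_false(flat$converged)
  expect_match(flat$flag, "flat")
  # monotone decreasing data bracket the ec50 inside the tested range
  r2 <- 100 / (1 + (d / 5)^1.2)
  fit2 <- fit_4pl(d, r2)
  expect_gt(fit2$ec50, min(d))
  expect_lt(fit2$ec50, max(d))
  expect_error(fit_4pl(c(1, 2, 3), c(90, 50, 20)), "at least 4")
})

test_that("cytotoxicity guard passes, fails and extrapolates as specified", {
  d <- c(0.5, 1, 3, 10, 30, 60)
  benign <- viability_curve("x", 1, d, 100 / (1 + (d / 500)^1.5))
  toxic <- viability_curve("x", 5, d, 100 / (1 + (d / 4)^2))
  ok <- cytotoxicity_guard(5, benign)
  expect_true(ok$pass)
  bad <- cytotoxicity_guard(5, toxic)
  expect_false(bad$pass)
  expect_match(bad$messages, "<")
  # both durations must pass
  both <- cytotoxicity_guard(5, list(benign, toxic))
  expect_false(both$pass)
  expect_named(both$viability, c("1d", "5d"))
  # BMC below the tested range: evaluated at the nearest bound, warns
  expect_warning(low <- cytotoxicity_guard(0.01, benign), "outside")
  expect_true(low$pass)
})
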