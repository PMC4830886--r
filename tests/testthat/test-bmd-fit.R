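test_that("slope is recovered from data simulated under the generating model", {
  truth_b <- 0.05
  spec <- dr_model_spec("quantal_linear")
  set.seed(21)
  d <- c(0, 2, 5, 10, 20, 40)
  p <- model_response(spec, c(g = 0, b = truth_b), d)
  qd <- quantal_dataset("x", d, rep(100, 6), rbinom(6, 100, p))
  fit <- fit_model(spec, qd)
  expect_true(fit$converged)
  expect_lt(abs(fit$params[["b"]] - truth_b) / truth_b, 0.15)
})

test_that("flat all-unaffected data drives the slope to its lower bound", {
  qd <- quantal_dataset("x", c(0, 5, 20, 60), rep(24, 4), c(0, 0, 0, 0))
  fit <- fit_model(dr_model_spec("quantal_linear"), qd)
  expect_true(fit$converged)
  expect_lt(fit$params[["b"]], 1e-6)
  expect_lt(model_response(fit$model, fit$params, 60), 0.01)
})

test_that("nested models respect the likelihood ordering", {
  set.seed(5)
  d <- c(0, 1, 3, 10, 30)
  qd <- quantal_dataset("x", d, rep(48, 5), c(2, 5, 16, 33, 44))
  ll1 <- fit_model(dr_model_spec("quantal_linear"), qd)$loglik
  ll_ms1 <- fit_model(dr_model_spec("multistage", degree = 1), qd)$loglik
  ll_ms2 <- fit_model(dr_model_spec("multistage", degree = 2), qd)$loglik
  # multistage degree 1 is the quantal-linear model
  expect_equal(ll_ms1, ll1, tolerance = 1e-5)
  expect_gte(ll_ms2, ll1 - 1e-6)
})

test_that("BMC closed forms match hand values and the root-search path", {
  qd <- quantal_dataset("x", c(0, 2, 5, 10, 20), rep(72, 5),
                        c(2, 10, 35, 60, 70))
  fit <- fit_model(dr_model_spec("quantal_linear"), qd)
  fit$params <- c(g = 0, b = 0.1)
  expect_equal(bmc_from_fit(fit, bmr = 0.5), log(2) / 0.1, tolerance = 1e-10)
  fit_ll <- fit_model(dr_model_spec("loglogistic"), qd)
  fit_ll$params <- c(g = 0, a = -2, b = 1)
  expect_equal(bmc_from_fit(fit_ll, bmr = 0.5), exp(2), tolerance = 1e-8)
  # monotone in the benchmark response
  expect_gt(bmc_from_fit(fit, bmr = 0.5), bmc_from_fit(fit, bmr = 0.1))
  # beyond-range error
  fit$params <- c(g = 0, b = 1e-6)
  expect_error(bmc_from_fit(fit, force_search = TRUE), "beyond tested range")
})

test_that("closed-form and root-search BMCs agree across random draws", {
  set.seed(13)
  qd <- quantal_dataset("x", c(0, 2, 5, 10, 20), rep(72, 5),
                        c(2, 10, 35, 60, 70))
  fit <- fit_model(dr_model_spec("quantal_linear"), qd)
  fit_ll <- fit_model(dr_model_spec("loglogistic"), qd)
  for (i in 1:200) {
    b <- 10^runif(1, -1.5, 0.5)
    g <- runif(1, 0, 0.3)
    bmr <- runif(1, 0.1, 0.9)
    fit$params <- c(g = g, b = b)
    cf <- bmc_from_fit(fit, bmr = bmr)
    rs <- bmc_from_fit(fit, bmr = bmr, force_search = TRUE)
    expect_lt(abs(cf - rs) / cf, 1e-6)
    a <- runif(1, -4, 1)
    bs <- runif(1, 0.5, 3)
    fit_ll$params <- c(g = g, a = a, b = bs)
    cf2 <- bmc_from_fit(fit_ll, bmr = bmr)
    if (cf2 < 10 * max(qd$concentration)) { # inside the search bracket
      rs2 <- bmc_from_fit(fit_ll, bmr = bmr, force_search = TRUE)
      expect_lt(abs(cf2 - rs2) / cf2, 1e-6)
    }
  }
})

test_that("goodness of fit: perfect fit, hand residual, thresholds, df floor", {
  # near-perfect agreement: residuals and chi-square vanish
  qd2 <- quantal_dataset("x", c(0, 5, 10, 20, 40), rep(100, 5),
                         round(100 * model_response(
                           dr_model_spec("quantal_linear"),
                           c(g = 0.1, b = log(2) / 10),
                           c(0, 5, 10, 20, 40))))
  fit2 <- fit_model(dr_model_spec("quantal_linear"), qd2)
  gof2 <- goodness_of_fit(fit2)
  expect_lt(gof2$chi_square, 0.05)
  expect_true(gof2$accepted)
  expect_equal(gof2$df, 3)
  # hand scaled residual: n = 100, y = 70, p = 0.5 -> (70-50)/5 = 4
  n <- 100; y <- 70; p <- 0.5
  expect_equal((y - n * p) / sqrt(n * p * (1 - p)), 4)
  qd3 <- quantal_dataset("x", c(0, 5, 10), rep(100, 3), c(50, 50, 70))
  fit3 <- fit_model(dr_model_spec("quantal_linear"), qd3)
  fit3$params <- c(g = 0.5, b = 1e-8)
  gof3 <- goodness_of_fit(fit3)
  expect_equal(max(abs(gof3$scaled_residuals)), 4, tolerance = 1e-4)
  expect_false(gof3$accepted) # residual beyond 2 and p tiny
  # df <= 0 is never accepted: 3 groups vs a 3-parameter model
  qd4 <- quantal_dataset("x", c(0, 5, 20), c(24, 24, 24), c(2, 12, 20))
  fit4 <- fit_model(dr_model_spec("loglogistic"), qd4)
  gof4 <- goodness_of_fit(fit4)
  expect_false(gof4$accepted)
  expect_equal(gof4$reason, "unidentifiable")
})

test_that("lowest accepted BMC is selected; no-accepted case is flagged", {
  mk <- function(bmc, p, npar = 2, accepted = TRUE, converged = TRUE) {
    list(fit = structure(list(model = dr_model_spec("quantal_linear"),
                              params = c(g = 0, b = 1), loglik = -10,
                              converged = converged, n_params = npar,
                              data = NULL), class = "dr_fit"),
         gof = structure(list(chi_square = 1, df = 2, p_value = p,
                              scaled_residuals = 0, accepted = accepted,
                              reason = ""), class = "gof_report"),
         bmc = bmc)
  }
  est <- select_bmc(list(mk(4.6, 0.5), mk(4.2, 0.4), mk(5.0, 0.9)))
  expect_equal(est$bmc, 4.2)
  expect_false(est$no_accepted_model)
  single <- select_bmc(list(mk(7.7, 0.3)))
  expect_equal(single$bmc, 7.7)
  expect_warning(none <- select_bmc(list(mk(4.6, 0.5, accepted = FALSE),
                                         mk(9.9, 0.8, accepted = FALSE))),
                 "no model accepted")
  expect_true(none$no_accepted_model)
  expect_equal(none$bmc, 9.9) # best-p fit carried for inspection
})

test_that("full BMC analysis runs all eight models and picks an accepted one", {
  spec <- dr_model_spec("quantal_linear")
  set.seed(33)
  d <- c(0, 0.5, 1.5, 4, 12, 36)
  p <- model_response(spec, c(g = 0.03, b = log(2) / 4), d)
  qd <- quantal_dataset("x", d, rep(72, 6), rbinom(6, 72, p))
  est <- bmc_d50(qd)
  expect_length(est$all_fits, 8)
  expect_named(est$all_fits, quantal_model_names(), ignore.order = TRUE)
  expect_false(est$no_accepted_model)
  expect_gt(est$bmc, 0)
  # minimum over accepted models
  acc <- Filter(function(x) isTRUE(x$gof$accepted) && is.finite(x$bmc),
                est$all_fits)
  expect_equal(est$bmc, min(vapply(acc, `[[`, numeric(1), "bmc")))
})
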