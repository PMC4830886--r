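# Independent oracles used across tests.

# Event-by-event bookkeeping simulator for the receiver compartment:
# given the true amount transported within each inter-sample interval,
# replays every withdrawal/dilution event and returns both the measured
# concentrations (what an analyst records) and the true cumulative
# transported amounts (what the correction formula must recover).
event_bookkeeping <- function(interval_amounts, basolateral_volume,
                              sample_volume) {
  q_baso <- 0
  measured <- true_cumulative <- numeric(length(interval_amounts))
  total <- 0
  for (k in seq_along(interval_amounts)) {
    q_baso <- q_baso + interval_amounts[k]
    total <- total + interval_amounts[k]
    conc <- q_baso / basolateral_volume
    measured[k] <- conc
    q_baso <- q_baso - conc * sample_volume # withdraw, replace with buffer
    true_cumulative[k] <- total
  }
  list(measured = measured, true_cumulative = true_cumulative)
}

# closed-form extra-risk BMC used as independent oracle where available
oracle_bmc <- function(model, params, bmr = 0.5) {
  switch(model,
    quantal_linear = -log(1 - bmr) / params[["b"]],
    loglogistic = exp((qlogis(bmr) - params[["a"]]) / params[["b"]]),
    weibull = (-log(1 - bmr) / params[["b"]])^(1 / params[["a"]]),
    gamma = qgamma(bmr, shape = params[["a"]]) / params[["b"]],
    logprobit = exp((qnorm(bmr) - params[["a"]]) / params[["b"]]),
    stop("no closed form for ", model)
  )
}

# generating parameters with a known BMC (extra risk 0.5) for each model
params_with_bmc50 <- function(model, bmc, degree = 2) {
  switch(model,
    quantal_linear = c(g = 0.04, b = log(2) / bmc),
    loglogistic = c(g = 0.04, a = -1.6 * log(bmc), b = 1.6),
    logprobit = c(g = 0.04, a = -1.2 * log(bmc), b = 1.2),
    weibull = c(g = 0.04, a = 1.5, b = log(2) / bmc^1.5),
    gamma = c(g = 0.04, a = 2, b = qgamma(0.5, 2) / bmc),
    logistic = {
      a <- -3
      p0 <- plogis(a)
      c(a = a, b = (qlogis(0.5 + 0.5 * p0) - a) / bmc)
    },
    probit = {
      a <- -2
      p0 <- pnorm(a)
      c(a = a, b = (qnorm(0.5 + 0.5 * p0) - a) / bmc)
    },
    multistage = {
      b1 <- 0.25 * log(2) / bmc
      b2 <- (log(2) - b1 * bmc) / bmc^2
      c(g = 0.04, beta1 = b1, beta2 = b2)
    }
  )
}

make_spec <- function(model, degree = 2) {
  dr_model_spec(model, degree = if (model == "multistage") degree)
}
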