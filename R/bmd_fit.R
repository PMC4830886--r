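# Maximum-likelihood fitting of the quantal models and benchmark
# concentration derivation.

# run expr with a local RNG state so fitting never disturbs the caller's seed
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# heuristic starting values: empirical background + slope from a
# linearising regression of the empirical response
heuristic_start <- function(spec, data) {
  info <- model_param_info(spec)
  frac <- (data$affected + 0.5) / (data$n + 1)
  ctrl <- data$concentration == 0
  g0 <- min(max(mean(frac[ctrl]), 1e-3), 0.5)
  d_pos <- data$concentration[!ctrl]
  f_pos <- frac[!ctrl]
  # crude ED50 guess: concentration whose response is nearest halfway
  target <- g0 + (1 - g0) / 2
  ed50 <- d_pos[which.min(abs(f_pos - target))]
  if (!length(ed50) || ed50 <= 0) ed50 <- stats::median(d_pos)
  start <- switch(spec$name,
    logistic = c(a = stats::qlogis(g0), b = 2 / ed50),
    probit = c(a = stats::qnorm(g0), b = 1 / ed50),
    loglogistic = c(g = g0, a = -log(ed50), b = 1.5),
    logprobit = c(g = g0, a = -log(ed50), b = 1.2),
    weibull = c(g = g0, a = 1.3, b = log(2) / ed50^1.3),
    gamma = c(g = g0, a = 1.5, b = stats::qgamma(0.5, 1.5) / ed50),
    quantal_linear = c(g = g0, b = log(2) / ed50),
    multistage = {
      k <- spec$degree
      b1 <- log(2) / ed50
      higher <- (b1 / ed50) * 0.5^seq_len(k - 1) # damped higher-order terms
      stats::setNames(c(g0, b1, higher),
                      c("g", paste0("beta", seq_len(k))))
    }
  )
  pmin(pmax(start, info$lower), info$upper)
}

#' Fit a dichotomous model by binomial maximum likelihood
#'
#' Maximises [binomial_loglik()] under the model's parameter constraints
#' with multi-start bounded quasi-Newton optimisation (`optim`,
#' `"L-BFGS-B"`). Starts are a deterministic heuristic (empirical
#' background, crude ED50 from the empirical response) plus seeded random
#' perturbations, so a fit is fully reproducible. The `converged` flag is
#' honest: if every start fails the result is returned non-converged, never
#' as an error.
#'
#' @param spec A [dr_model_spec()].
#' @param data A [quantal_dataset()] with >= 3 groups, at least one of them
#'   non-control.
#' @param n_starts Number of optimisation starts (>= 1); default 8.
#' @param seed Seed for the random start perturbations; default 101.
#' @return Object of class `dr_fit`: list with `model`, `params` (named),
#'   `loglik`, `converged`, `n_params`, `data`.
#' @examples
#' qd <- quantal_dataset("x", c(0, 2, 5, 10, 20),
#'                       rep(72, 5), c(2, 10, 35, 60, 70))
#' fit <- fit_model(dr_model_spec("quantal_linear"), qd)
#' fit$params
#' @export
fit_model <- function(spec, data, n_starts = 8, seed = 101) {
  stopifnot(inherits(spec, "dr_model_spec"),
            inherits(data, "quantal_dataset"))
  if (nrow(data) < 3) stop("need at least 3 dose groups", call. = FALSE)
  if (all(data$concentration == 0)) {
    stop("need at least one non-control group", call. = FALSE)
  }
  info <- model_param_info(spec)
  nll <- function(theta) {
    names(theta) <- info$names
    -binomial_loglik(spec, theta, data)
  }
  base_start <- heuristic_start(spec, data)
  starts <- list(base_start)
  if (n_starts > 1) {
    with_local_seed(seed, {
      for (i in seq_len(n_starts - 1)) {
        jitter <- base_start * exp(stats::rnorm(length(base_start), 0, 0.6))
        # additive jitter for parameters that may be <= 0 (intercepts)
        jitter <- jitter + stats::rnorm(length(base_start), 0, 0.3)
        starts[[i + 1]] <- pmin(pmax(jitter, info$lower), info$upper)
      }
    })
  }
  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      stats::optim(st, nll, method = "L-BFGS-B",
                   lower = info$lower, upper = info$upper,
                   control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    return(structure(list(model = spec, params = base_start,
                          loglik = -Inf, converged = FALSE,
                          n_params = length(info$names), data = data),
                     class = "dr_fit"))
  }
  params <- stats::setNames(best$par, info$names)
  structure(list(model = spec, params = params,
                 loglik = -best$value,
                 converged = TRUE,
                 n_params = length(info$names),
                 data = data),
            class = "dr_fit")
}

#' @export
print.dr_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s): loglik %.3f\n", x$model$name,
              if (x$converged) "converged" else "NOT converged", x$loglik))
  print(round(x$params, 5))
  invisible(x)
}

extra_risk <- function(fit, d) {
  p0 <- model_response(fit$model, fit$params, 0)
  (model_response(fit$model, fit$params, d) - p0) / (1 - p0)
}

#' Benchmark concentration from a fitted model
#'
#' Solves extra risk `(p(d) - p(0)) / (1 - p(0)) = bmr` for the
#' concentration d. Closed forms are used for the quantal-linear
#' (`log(1/(1 - bmr)) / b`) and log-logistic
#' (`exp((qlogis(bmr) - a) / b)`) models; all other models use a bracketed
#' root search on `(0, 10 x max tested concentration]` with relative
#' tolerance 1e-8.
#'
#' @param fit A converged [fit_model()] result.
#' @param bmr Benchmark response (extra risk), default 0.5 — the
#'   concentration halving differentiation relative to control.
#' @param risk_type Only `"extra"` is supported.
#' @param force_search Use the root search even where a closed form exists
#'   (for cross-checking).
#' @return BMC in uM.
#' @examples
#' qd <- quantal_dataset("x", c(0, 2, 5, 10, 20),
#'                       rep(72, 5), c(2, 10, 35, 60, 70))
#' fit <- fit_model(dr_model_spec("quantal_linear"), qd)
#' bmc_from_fit(fit, bmr = 0.5)
#' @export
bmc_from_fit <- function(fit, bmr = 0.5, risk_type = "extra",
                         force_search = FALSE) {
  stopifnot(inherits(fit, "dr_fit"))
  risk_type <- match.arg(risk_type, "extra")
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  if (bmr <= 0 || bmr >= 1) stop("bmr must be in (0, 1)", call. = FALSE)
  p <- fit$params
  if (!force_search) {
    if (fit$model$name == "quantal_linear") {
      return(unname(log(1 / (1 - bmr)) / p["b"]))
    }
    if (fit$model$name == "loglogistic") {
      return(unname(exp((stats::qlogis(bmr) - p["a"]) / p["b"])))
    }
  }
  max_dose <- max(fit$data$concentration)
  hi <- 10 * max_dose
  f <- function(d) extra_risk(fit, d) - bmr
  if (f(hi) < 0) stop("BMC beyond tested range", call. = FALSE)
  lo <- hi * 1e-12
  while (f(lo) > 0) lo <- lo / 10
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-8 * hi)
  # polish to relative tolerance 1e-8
  stats::uniroot(f, c(root$root * (1 - 1e-4), min(root$root * (1 + 1e-4), hi)),
                 tol = 1e-8 * root$root, extendInt = "upX")$root
}

#' Goodness of fit of a quantal model
#'
#' Pearson chi-square over dose groups with df = groups - number of model
#' parameters, upper-tail p-value, and scaled residuals
#' `(y - n p) / sqrt(n p (1 - p))` per group. A model is accepted when the
#' p-value is at least `p_min` and no scaled residual exceeds
#' `residual_max` in magnitude. With df <= 0 the fit is unidentifiable and
#' never accepted.
#'
#' @param fit A converged [fit_model()] result.
#' @param data A [quantal_dataset()]; defaults to the data the model was
#'   fitted to.
#' @param p_min Minimum acceptable p-value (default 0.1).
#' @param residual_max Maximum acceptable |scaled residual| (default 2).
#' @return Object of class `gof_report`: list with `chi_square`, `df`,
#'   `p_value`, `scaled_residuals`, `accepted`, `reason`.
#' @export
goodness_of_fit <- function(fit, data = fit$data, p_min = 0.1,
                            residual_max = 2) {
  stopifnot(inherits(fit, "dr_fit"), inherits(data, "quantal_dataset"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  eps <- 1e-10
  p <- model_response(fit$model, fit$params, data$concentration)
  p <- pmin(pmax(p, eps), 1 - eps)
  expected <- data$n * p
  sd_bin <- sqrt(data$n * p * (1 - p))
  resid <- (data$affected - expected) / sd_bin
  chi2 <- sum(resid^2)
  df <- nrow(data) - fit$n_params
  if (df <= 0) {
    return(structure(list(chi_square = chi2, df = df, p_value = NA_real_,
                          scaled_residuals = resid, accepted = FALSE,
                          reason = "unidentifiable"),
                     class = "gof_report"))
  }
  pval <- stats::pchisq(chi2, df, lower.tail = FALSE)
  ok <- pval >= p_min && max(abs(resid)) <= residual_max
  reason <- if (ok) "accepted" else if (pval < p_min) {
    sprintf("p = %.3f < %.2f", pval, p_min)
  } else {
    sprintf("max |scaled residual| = %.2f > %g", max(abs(resid)), residual_max)
  }
  structure(list(chi_square = chi2, df = df, p_value = pval,
                 scaled_residuals = resid, accepted = ok, reason = reason),
            class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat(sprintf("Pearson chi-square %.3f on %d df, p = %s -> %s (%s)\n",
              x$chi_square, x$df,
              if (is.na(x$p_value)) "NA" else sprintf("%.3f", x$p_value),
              if (x$accepted) "accepted" else "rejected", x$reason))
  invisible(x)
}

#' Select the reported BMC from a set of candidate fits
#'
#' Filters to converged fits with acceptable goodness of fit and a finite
#' BMC and reports the lowest BMC among them (ties broken by higher GOF
#' p-value, then fewer parameters). When no model is accepted the estimate
#' is flagged and carries the best-p fit's BMC for inspection.
#'
#' @param all_fits List of candidates, each a list with elements `fit`
#'   (`dr_fit`), `gof` (`gof_report`) and `bmc` (uM or NA).
#' @param bmr The benchmark response the BMCs were computed at.
#' @return Object of class `bmc_estimate`: list with `bmc`, `bmr`,
#'   `risk_type`, `selected_model`, `no_accepted_model` flag and
#'   `all_fits`.
#' @export
select_bmc <- function(all_fits, bmr = 0.5) {
  stopifnot(length(all_fits) >= 1)
  ok <- vapply(all_fits, function(x) {
    isTRUE(x$fit$converged) && isTRUE(x$gof$accepted) &&
      is.finite(x$bmc) && x$bmc > 0
  }, logical(1))
  if (any(ok)) {
    cand <- all_fits[ok]
    bmcs <- vapply(cand, `[[`, numeric(1), "bmc")
    pvals <- vapply(cand, function(x) x$gof$p_value, numeric(1))
    npar <- vapply(cand, function(x) x$fit$n_params, numeric(1))
    ord <- order(bmcs, -pvals, npar)
    chosen <- cand[[ord[1]]]
    return(structure(list(bmc = chosen$bmc, bmr = bmr, risk_type = "extra",
                          selected_model = chosen$fit$model,
                          no_accepted_model = FALSE, all_fits = all_fits),
                     class = "bmc_estimate"))
  }
  # fall back to the best-fitting (highest p) converged model, flagged
  conv <- all_fits[vapply(all_fits, function(x) isTRUE(x$fit$converged),
                          logical(1))]
  if (!length(conv)) {
    return(structure(list(bmc = NA_real_, bmr = bmr, risk_type = "extra",
                          selected_model = NULL, no_accepted_model = TRUE,
                          all_fits = all_fits),
                     class = "bmc_estimate"))
  }
  pvals <- vapply(conv, function(x) {
    if (is.na(x$gof$p_value)) -Inf else x$gof$p_value
  }, numeric(1))
  chosen <- conv[[which.max(pvals)]]
  warning("no model accepted by goodness-of-fit screening; ",
          "reporting best-p fit (", chosen$fit$model$name, ") flagged",
          call. = FALSE)
  structure(list(bmc = chosen$bmc, bmr = bmr, risk_type = "extra",
                 selected_model = chosen$fit$model,
                 no_accepted_model = TRUE, all_fits = all_fits),
            class = "bmc_estimate")
}

#' @export
print.bmc_estimate <- function(x, ...) {
  cat(sprintf("BMC (bmr = %g, %s risk): %.4g uM [%s]%s\n", x$bmr,
              x$risk_type, x$bmc,
              if (!is.null(x$selected_model)) x$selected_model$name else "-",
              if (x$no_accepted_model) " (NO ACCEPTED MODEL)" else ""))
  invisible(x)
}

#' Full benchmark-concentration analysis of a quantal dataset
#'
#' Fits the eight standard dichotomous models (multistage at the given or
#' default degree), screens each by goodness of fit, derives the BMC at the
#' requested benchmark response for every converged fit, and selects the
#' lowest BMC among accepted models. The default `bmr = 0.5` with extra
#' risk gives the concentration producing a 50 % reduction in
#' differentiation relative to control when the control affected rate is
#' near zero (the BMC50 of the embryoid-body assay).
#'
#' @param data A [quantal_dataset()].
#' @param bmr Benchmark response (extra risk), default 0.5.
#' @param models Character vector of model names; default all eight.
#' @param multistage_degree Degree of the multistage model; default
#'   `min(groups - 2, 3)` (at least 1).
#' @param p_min,residual_max Goodness-of-fit acceptance thresholds (see
#'   [goodness_of_fit()]).
#' @param restricted Restrict shape/power parameters to >= 1.
#' @param seed Optimiser multi-start seed.
#' @return A `bmc_estimate` (see [select_bmc()]); `all_fits` carries every
#'   model's fit, GOF report and BMC.
#' @examples
#' qd <- quantal_dataset("x", c(0, 1, 3, 10, 30),
#'                       rep(72, 5), c(3, 8, 30, 58, 70))
#' est <- bmc_d50(qd)
#' est$bmc
#' @export
bmc_d50 <- function(data, bmr = 0.5, models = quantal_model_names(),
                    multistage_degree = NULL, p_min = 0.1, residual_max = 2,
                    restricted = TRUE, seed = 101) {
  stopifnot(inherits(data, "quantal_dataset"))
  if (is.null(multistage_degree)) {
    multistage_degree <- max(min(nrow(data) - 2L, 3L), 1L)
  }
  all_fits <- lapply(models, function(m) {
    spec <- dr_model_spec(m,
                          degree = if (m == "multistage") multistage_degree,
                          restricted = restricted)
    fit <- fit_model(spec, data, seed = seed)
    if (!fit$converged) {
      return(list(fit = fit,
                  gof = structure(list(chi_square = NA_real_, df = NA_integer_,
                                       p_value = NA_real_,
                                       scaled_residuals = NULL,
                                       accepted = FALSE,
                                       reason = "not converged"),
                                  class = "gof_report"),
                  bmc = NA_real_))
    }
    gof <- goodness_of_fit(fit, data, p_min = p_min,
                           residual_max = residual_max)
    bmc <- tryCatch(bmc_from_fit(fit, bmr = bmr), error = function(e) NA_real_)
    list(fit = fit, gof = gof, bmc = bmc)
  })
  names(all_fits) <- models
  select_bmc(all_fits, bmr = bmr)
}
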