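#' Names of the supported dichotomous dose-response models
#'
#' The standard suite of eight quantal models used in benchmark-dose
#' modelling of dichotomous endpoints.
#' @return Character vector of model names.
#' @export
quantal_model_names <- function() {
  c("gamma", "logistic", "loglogistic", "probit", "logprobit",
    "multistage", "weibull", "quantal_linear")
}

#' Dichotomous model specification
#'
#' @param name One of [quantal_model_names()].
#' @param degree Polynomial degree, multistage only (>= 1).
#' @param restricted Restrict shape/power parameters to >= 1 (the
#'   conventional restricted forms that keep the response finite-sloped at
#'   dose 0)? Default `TRUE`.
#' @return An object of class `dr_model_spec`.
#' @examples
#' dr_model_spec("multistage", degree = 2)
#' @export
dr_model_spec <- function(name, degree = NULL, restricted = TRUE) {
  name <- match.arg(name, quantal_model_names())
  if (name == "multistage") {
    if (is.null(degree)) degree <- 2L
    degree <- as.integer(degree)
    if (degree < 1L) stop("multistage degree must be >= 1", call. = FALSE)
  } else {
    if (!is.null(degree)) {
      stop("'degree' applies to the multistage model only", call. = FALSE)
    }
    degree <- NA_integer_
  }
  structure(list(name = name, degree = degree, restricted = restricted),
            class = "dr_model_spec")
}

#' @export
print.dr_model_spec <- function(x, ...) {
  cat(sprintf("Quantal model: %s%s%s\n", x$name,
              if (!is.na(x$degree)) sprintf(" (degree %d)", x$degree) else "",
              if (x$restricted) "" else " [unrestricted]"))
  invisible(x)
}

# parameter layout per model: names, lower and upper optimisation bounds
model_param_info <- function(spec) {
  slope_max <- 1e3
  switch(spec$name,
    logistic = list(names = c("a", "b"),
                    lower = c(-18, 1e-8), upper = c(18, slope_max)),
    probit = list(names = c("a", "b"),
                  lower = c(-18, 1e-8), upper = c(18, slope_max)),
    loglogistic = list(names = c("g", "a", "b"),
                       lower = c(0, -18, 1e-8),
                       upper = c(1 - 1e-6, 18, 40)),
    logprobit = list(names = c("g", "a", "b"),
                     lower = c(0, -18, 1e-8),
                     upper = c(1 - 1e-6, 18, 40)),
    weibull = list(names = c("g", "a", "b"),
                   lower = c(0, if (spec$restricted) 1 else 1e-8, 1e-8),
                   upper = c(1 - 1e-6, 18, slope_max)),
    gamma = list(names = c("g", "a", "b"),
                 lower = c(0, if (spec$restricted) 1 else 1e-8, 1e-8),
                 upper = c(1 - 1e-6, 18, slope_max)),
    quantal_linear = list(names = c("g", "b"),
                          lower = c(0, 1e-8), upper = c(1 - 1e-6, slope_max)),
    multistage = {
      k <- spec$degree
      list(names = c("g", paste0("beta", seq_len(k))),
           lower = c(0, rep(0, k)),
           upper = c(1 - 1e-6, rep(slope_max, k)))
    }
  )
}

#' Response probability of a dichotomous dose-response model
#'
#' Evaluates the probability of the quantal outcome ("affected": here, an
#' embryoid body failing to differentiate) at the given concentrations.
#' Forms, with background `g`, intercept `a`, slope `b`, power/shape `a`
#' (weibull/gamma) and multistage coefficients `beta1..betak`:
#'
#' * logistic: `1 / (1 + exp(-(a + b d)))`
#' * probit: `pnorm(a + b d)`
#' * log-logistic: `g + (1 - g) / (1 + exp(-(a + b log(d))))`
#' * log-probit: `g + (1 - g) pnorm(a + b log(d))`
#' * weibull: `g + (1 - g)(1 - exp(-b d^a))`
#' * gamma: `g + (1 - g) pgamma(b d, shape = a)` (regularised incomplete
#'   gamma)
#' * quantal-linear: `g + (1 - g)(1 - exp(-b d))`
#' * multistage: `g + (1 - g)(1 - exp(-sum(beta_i d^i)))`
#'
#' Log-dose models return `g` at d = 0 by definition (the control group
#' enters the likelihood through the background only).
#'
#' @param spec A [dr_model_spec()].
#' @param params Named numeric vector as given by the model's parameter
#'   layout (see above); checked against the model's admissible bounds.
#' @param concentration Concentration(s), uM, >= 0.
#' @return Probability vector in `[0, 1]`, same length as `concentration`.
#' @examples
#' sp <- dr_model_spec("loglogistic")
#' model_response(sp, c(g = 0.1, a = 0, b = 1), 1) # 0.55
#' @export
model_response <- function(spec, params, concentration) {
  stopifnot(inherits(spec, "dr_model_spec"))
  info <- model_param_info(spec)
  params <- params[info$names]
  if (anyNA(params)) {
    stop("params must contain: ", paste(info$names, collapse = ", "),
         call. = FALSE)
  }
  tol <- 1e-9
  if (any(params < info$lower - tol) || any(params > info$upper + tol)) {
    stop("parameters outside admissible bounds for model ", spec$name,
         call. = FALSE)
  }
  d <- concentration
  if (any(d < 0)) stop("concentration must be >= 0", call. = FALSE)
  p <- switch(spec$name,
    logistic = stats::plogis(params["a"] + params["b"] * d),
    probit = stats::pnorm(params["a"] + params["b"] * d),
    loglogistic = {
      g <- params["g"]
      out <- rep(g, length(d))
      pos <- d > 0
      out[pos] <- g + (1 - g) *
        stats::plogis(params["a"] + params["b"] * log(d[pos]))
      out
    },
    logprobit = {
      g <- params["g"]
      out <- rep(g, length(d))
      pos <- d > 0
      out[pos] <- g + (1 - g) *
        stats::pnorm(params["a"] + params["b"] * log(d[pos]))
      out
    },
    weibull = params["g"] + (1 - params["g"]) *
      (1 - exp(-params["b"] * d^params["a"])),
    gamma = params["g"] + (1 - params["g"]) *
      stats::pgamma(params["b"] * d, shape = params["a"]),
    quantal_linear = params["g"] + (1 - params["g"]) *
      (1 - exp(-params["b"] * d)),
    multistage = {
      k <- spec$degree
      betas <- params[paste0("beta", seq_len(k))]
      hazard <- outer(d, seq_len(k), `^`) %*% betas
      params["g"] + (1 - params["g"]) * (1 - exp(-as.numeric(hazard)))
    }
  )
  unname(pmin(pmax(p, 0), 1))
}

#' Quantal dataset: per-concentration well counts
#'
#' @param compound_id Compound identifier.
#' @param concentration Concentrations in uM (distinct; must include 0, the
#'   solvent control).
#' @param n Wells scored per concentration.
#' @param affected Wells showing the adverse outcome (non-differentiated),
#'   `0 <= affected <= n`.
#' @return Object of class `quantal_dataset` (a data.frame sorted by
#'   concentration with attribute `compound_id`).
#' @examples
#' quantal_dataset("x", c(0, 1, 10), c(24, 24, 24), c(1, 5, 20))
#' @export
quantal_dataset <- function(compound_id, concentration, n, affected) {
  if (length(concentration) != length(n) ||
      length(n) != length(affected)) {
    stop("'concentration', 'n' and 'affected' lengths differ", call. = FALSE)
  }
  if (anyDuplicated(concentration)) {
    stop("concentrations must be distinct (pool counts first)", call. = FALSE)
  }
  if (any(concentration < 0)) stop("negative concentration", call. = FALSE)
  if (!0 %in% concentration) {
    stop("a zero-concentration (solvent control) group is required",
         call. = FALSE)
  }
  if (any(affected < 0) || any(affected > n)) {
    stop("'affected' must satisfy 0 <= affected <= n", call. = FALSE)
  }
  ord <- order(concentration)
  structure(
    data.frame(concentration = concentration[ord], n = n[ord],
               affected = affected[ord]),
    compound_id = as.character(compound_id),
    class = c("quantal_dataset", "data.frame")
  )
}

#' Binomial log-likelihood of a quantal model
#'
#' `sum(y log p + (n - y) log(1 - p))` over dose groups, with predicted
#' probabilities clamped to `[eps, 1 - eps]` (eps = 1e-10) so the
#' likelihood stays finite at boundary fits.
#'
#' @param spec A [dr_model_spec()].
#' @param params Named parameter vector.
#' @param data A [quantal_dataset()].
#' @param eps Clamping bound for predicted probabilities.
#' @return Log-likelihood (finite).
#' @export
binomial_loglik <- function(spec, params, data, eps = 1e-10) {
  stopifnot(inherits(data, "quantal_dataset"))
  p <- model_response(spec, params, data$concentration)
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(data$affected * log(p) + (data$n - data$affected) * log1p(-p))
}
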