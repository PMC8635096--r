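# Structural placebo-response model: saturating Emax time course on the
# change-from-baseline ESSDAI scale, with a linear centered covariate model
# on Emax, additive inter-trial variability on Emax and exponential
# (log-scale) inter-trial variability on ET50.
#
# Sign convention: Emax is stored as a positive magnitude; predictions are
# negative changes (improvement). Emax for a trial may become negative at
# very low baselines (the covariate line is not clamped).

#' Construct a set of placebo-response model parameters
#'
#' Bundles the fixed effects, covariate coefficients, inter-trial
#' standard deviations and residual standard deviation of the Emax
#' time-course model
#' \deqn{E_{ij} = -\mathrm{Emax}_i \frac{t_j}{\mathrm{ET50}_i + t_j} +
#'   \epsilon_{ij}/\sqrt{N_{ij}}}
#' where \eqn{\mathrm{Emax}_i = \theta_{Emax} + \sum_c \beta_c (x_{ic} -
#' \bar x_c) + \eta_{1i}} and \eqn{\mathrm{ET50}_i = \theta_{ET50}
#' e^{\eta_{2i}}}.
#'
#' @param theta_emax Typical maximum placebo response (ESSDAI points,
#'   positive = improvement magnitude) at the covariate reference values.
#' @param theta_et50 Typical time to half-maximal response, weeks (> 0).
#' @param covariate_effects Named list; each element a numeric vector
#'   `c(coef = ..., center = ...)` giving the linear coefficient on Emax
#'   and the centering constant for that covariate.
#' @param omega_emax Standard deviation of the additive trial-level
#'   random effect on Emax (ESSDAI points, >= 0).
#' @param omega_et50 Standard deviation of the trial-level random effect
#'   on log ET50 (dimensionless, >= 0).
#' @param sigma Residual standard deviation before the \eqn{1/\sqrt{N}}
#'   sample-size scaling (ESSDAI points, >= 0; zero only meaningful for
#'   noise-free simulation, not estimation).
#'
#' @return An object of class `model_parameters`.
#' @seealso [default_parameters()] for the published final-model estimates.
#' @export
#' @examples
#' p <- model_parameters(4.44, 12.2,
#'   covariate_effects = list(baseline_essdai = c(coef = 0.552, center = 10.1)))
#' typical_response(p, baseline = 13, time = 24)
model_parameters <- function(theta_emax, theta_et50,
                             covariate_effects = list(),
                             omega_emax = 0, omega_et50 = 0,
                             sigma = 1) {
  stopifnot(is.numeric(theta_emax), length(theta_emax) == 1L, is.finite(theta_emax))
  if (!is.numeric(theta_et50) || length(theta_et50) != 1L || theta_et50 <= 0)
    stop("theta_et50 must be a single positive number (weeks)")
  if (omega_emax < 0 || omega_et50 < 0) stop("omega values must be >= 0")
  if (sigma < 0) stop("sigma must be >= 0")
  if (length(covariate_effects)) {
    if (is.null(names(covariate_effects)) || any(!nzchar(names(covariate_effects))))
      stop("covariate_effects must be a named list")
    for (j in seq_along(covariate_effects)) {
      ce <- covariate_effects[[j]]
      if (!is.numeric(ce) || !all(c("coef", "center") %in% names(ce)))
        stop("covariate effect for '", names(covariate_effects)[j],
             "' must be c(coef = , center = )")
      covariate_effects[[j]] <- ce[c("coef", "center")]
    }
  }
  structure(list(theta_emax = theta_emax,
                 theta_et50 = theta_et50,
                 covariate_effects = covariate_effects,
                 omega_emax = omega_emax,
                 omega_et50 = omega_et50,
                 sigma = sigma),
            class = "model_parameters")
}

#' Published final-model parameter estimates
#'
#' The final mixed-effects model estimates for the pooled placebo corpus:
#' typical Emax 4.44 ESSDAI points at the reference baseline 10.1, ET50
#' 12.2 weeks, baseline-ESSDAI coefficient 0.552 points per point,
#' inter-trial SDs 0.563 (Emax, additive) and 0.794 (log ET50), residual
#' SD 1.661 before sample-size scaling.
#'
#' @param omega_scale Either `"sd"` (default; the inter-trial rows are
#'   standard deviations) or `"variance"` (they are variances and are
#'   square-rooted here). Provided as a sensitivity switch because
#'   reporting conventions for trial-level variability differ.
#' @return A [model_parameters()] object.
#' @export
default_parameters <- function(omega_scale = c("sd", "variance")) {
  omega_scale <- match.arg(omega_scale)
  om <- c(0.563, 0.794)
  if (omega_scale == "variance") om <- sqrt(om)
  model_parameters(
    theta_emax = 4.44, theta_et50 = 12.2,
    covariate_effects = list(baseline_essdai = c(coef = 0.552, center = 10.1)),
    omega_emax = om[1], omega_et50 = om[2], sigma = 1.661)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Placebo-response Emax time-course model parameters\n")
  cat(sprintf("  theta_Emax : %8.4g ESSDAI points\n", x$theta_emax))
  cat(sprintf("  theta_ET50 : %8.4g weeks\n", x$theta_et50))
  for (nm in names(x$covariate_effects)) {
    ce <- x$covariate_effects[[nm]]
    cat(sprintf("  %s on Emax: coef %.4g (centered at %.4g)\n",
                nm, ce[["coef"]], ce[["center"]]))
  }
  cat(sprintf("  omega_Emax : %8.4g (additive SD)\n", x$omega_emax))
  cat(sprintf("  omega_ET50 : %8.4g (log-scale SD)\n", x$omega_et50))
  cat(sprintf("  sigma      : %8.4g (residual SD before 1/sqrt(N))\n", x$sigma))
  invisible(x)
}

# pull a named covariate value out of a one-row data.frame / named list
.cov_value <- function(cov, nm) {
  v <- if (is.data.frame(cov)) cov[[nm]][1] else cov[[nm]]
  if (is.null(v) || is.na(v))
    stop("required covariate '", nm, "' is missing")
  as.numeric(v)
}

#' Trial-level Emax from covariates and random effect
#'
#' Evaluates the covariate model on Emax,
#' \eqn{\mathrm{Emax}_i = \theta_{Emax} + \sum_c \beta_c (x_{ic} -
#' \bar x_c) + \eta_{1i}}.
#'
#' @param params A [model_parameters()] object.
#' @param cov Named list or one-row data frame holding every covariate
#'   named in `params$covariate_effects`.
#' @param eta_emax Additive trial random effect on Emax (default 0).
#' @return Trial Emax in ESSDAI points (may be negative at extreme
#'   covariate values; the linear covariate model is not clamped).
#' @export
trial_emax <- function(params, cov, eta_emax = 0) {
  stopifnot(inherits(params, "model_parameters"), is.finite(eta_emax))
  e <- params$theta_emax
  for (j in seq_along(params$covariate_effects)) {
    ce <- params$covariate_effects[[j]]
    e <- e + ce[["coef"]] *
      (.cov_value(cov, names(params$covariate_effects)[j]) - ce[["center"]])
  }
  unname(e + eta_emax)
}

#' Trial-level ET50 from the exponential random effect
#'
#' \eqn{\mathrm{ET50}_i = \theta_{ET50} e^{\eta_{2i}}}; strictly positive
#' by construction.
#'
#' @inheritParams trial_emax
#' @param eta_et50 Trial random effect on log ET50 (default 0).
#' @return Trial ET50 in weeks.
#' @export
trial_et50 <- function(params, eta_et50 = 0) {
  stopifnot(inherits(params, "model_parameters"), is.finite(eta_et50))
  unname(params$theta_et50 * exp(eta_et50))
}

#' Model-predicted change from baseline for one trial
#'
#' Deterministic part of the model:
#' \eqn{-\mathrm{Emax}_i \, t / (\mathrm{ET50}_i + t)}. Zero at time 0
#' and approaching \eqn{-\mathrm{Emax}_i} as \eqn{t \to \infty}.
#'
#' @inheritParams trial_emax
#' @param etas List or numeric vector with elements `eta_emax` and
#'   `eta_et50` (both default 0).
#' @param time Time since randomization in weeks (vectorized, all >= 0).
#' @return Predicted ESSDAI change from baseline (negative = improvement).
#' @export
predict_change <- function(params, cov, etas = list(eta_emax = 0, eta_et50 = 0),
                           time) {
  if (any(!is.finite(time)) || any(time < 0))
    stop("time must be finite and >= 0 (weeks)")
  e1 <- if (!is.null(etas$eta_emax)) etas$eta_emax else etas[["eta_emax"]]
  e2 <- if (!is.null(etas$eta_et50)) etas$eta_et50 else etas[["eta_et50"]]
  emax_i <- trial_emax(params, cov, e1)
  et50_i <- trial_et50(params, e2)
  -emax_i * time / (et50_i + time)
}

#' Typical placebo response at a given baseline
#'
#' The population-level prediction: [predict_change()] with both random
#' effects at zero and only the baseline ESSDAI covariate supplied.
#'
#' @inheritParams predict_change
#' @param baseline Baseline ESSDAI score (points).
#' @return Typical ESSDAI change from baseline at each `time`.
#' @export
#' @examples
#' typical_response(default_parameters(), baseline = 8, time = c(12, 24, 48))
typical_response <- function(params, baseline, time) {
  predict_change(params, cov = list(baseline_essdai = baseline),
                 etas = list(eta_emax = 0, eta_et50 = 0), time = time)
}

#' Write model parameters to a JSON file
#'
#' Flat JSON serialization with explicit field names; exact round-trip
#' with [read_parameters()].
#'
#' @param params A [model_parameters()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "model_parameters"))
  x <- list(theta_emax = params$theta_emax,
            theta_et50 = params$theta_et50,
            covariate_effects = lapply(params$covariate_effects, as.list),
            omega_emax = params$omega_emax,
            omega_et50 = params$omega_et50,
            sigma = params$sigma)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read model parameters from a JSON file
#'
#' @param path File written by [write_parameters()].
#' @return A [model_parameters()] object.
#' @export
read_parameters <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ce <- lapply(x$covariate_effects, function(e) c(coef = e$coef, center = e$center))
  model_parameters(x$theta_emax, x$theta_et50, covariate_effects = ce,
                   omega_emax = x$omega_emax, omega_et50 = x$omega_et50,
                   sigma = x$sigma)
}
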