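# Monte-Carlo simulation of the typical placebo response: the
# deterministic median surface over baselines and times, and the 95%
# confidence band from fixed-effect parameter uncertainty (no trial
# random effects — the band describes the typical value, not a new
# trial).

#' Deterministic typical-response grid
#'
#' Evaluates [typical_response()] on a baseline-by-time grid.
#'
#' @param params A [model_parameters()] object.
#' @param baselines Vector of baseline ESSDAI scores.
#' @param times Vector of times (weeks).
#' @return Numeric matrix (baselines in rows, times in columns) of
#'   typical ESSDAI changes from baseline; dimnames carry the grid.
#' @export
#' @examples
#' typical_table(default_parameters(), c(3, 8, 13), c(12, 24, 48))
typical_table <- function(params, baselines, times) {
  stopifnot(inherits(params, "model_parameters"),
            length(baselines) >= 1, length(times) >= 1)
  out <- vapply(times, function(tt)
    vapply(baselines, function(b) typical_response(params, b, tt), numeric(1)),
    numeric(length(baselines)))
  out <- matrix(out, nrow = length(baselines), ncol = length(times),
                dimnames = list(baseline = as.character(baselines),
                                time_weeks = as.character(times)))
  out
}

#' Monte-Carlo confidence band for the typical placebo response
#'
#' Draws the fixed effects (theta_Emax, log theta_ET50, covariate
#' coefficients) `n_draws` times from their asymptotic multivariate
#' normal on the estimation (transformed) scale — so ET50 stays positive
#' by construction — evaluates the typical response per draw, and
#' reports the 2.5/50/97.5 percentiles per time point. Only parameter
#' uncertainty enters: inter-trial variability is deliberately excluded
#' because the band describes the typical (population) value. If the fit
#' carries no usable covariance but has per-parameter RSEs, independent
#' normal draws are used instead, with theta_ET50 drawn lognormally.
#'
#' @param fit A converged [fit_model()] result with a covariance or
#'   RSEs.
#' @param baseline Baseline ESSDAI score for the band.
#' @param times Vector of times (weeks).
#' @param n_draws Number of Monte-Carlo draws (default 10000).
#' @param seed Integer seed.
#' @return Object of class `typical_band`: list with `band` (data frame
#'   `time_weeks, median, lo95, hi95`), `baseline`, `n_draws`.
#' @export
typical_ci <- function(fit, baseline, times, n_draws = 10000L, seed = 1L) {
  stopifnot(inherits(fit, "placebo_fit"), length(baseline) == 1L,
            n_draws >= 1)
  params <- fit$params
  pn <- names(fit$coef)
  fixed_idx <- which(!pn %in% c("omega_emax", "omega_et50", "sigma"))
  draws <- NULL
  if (!is.null(fit$covariance)) {
    mu <- fit$coef[fixed_idx]
    Sig <- .symm(fit$covariance[fixed_idx, fixed_idx, drop = FALSE])
    draws <- withr_seed(seed, MASS::mvrnorm(n_draws, mu, Sig))
    if (is.null(dim(draws))) draws <- matrix(draws, ncol = length(mu))
    colnames(draws) <- pn[fixed_idx]
  } else if (all(is.finite(fit$rse_pct[fixed_idx]))) {
    # fallback: independent normals from the RSEs; ET50 lognormal
    draws <- withr_seed(seed, {
      cols <- lapply(fixed_idx, function(i) {
        nm <- pn[i]
        est <- fit$coef[i]              # transformed scale
        if (nm == "theta_et50") rnorm(n_draws, est, fit$rse_pct[i] / 100)
        else {
          nat <- est
          rnorm(n_draws, nat, abs(fit$se[i]))
        }
      })
      m <- do.call(cbind, cols); colnames(m) <- pn[fixed_idx]; m
    })
  } else {
    stop("fit carries no usable covariance or RSE; cannot build a band")
  }
  covariates <- fit$covariates
  centers <- fit$centers
  curves <- apply(draws, 1, function(par_fixed) {
    th_emax <- par_fixed[["theta_emax"]]
    et50 <- exp(par_fixed[["theta_et50"]])
    emax_b <- th_emax
    for (nm in covariates) {
      if (nm == "baseline_essdai")
        emax_b <- emax_b + par_fixed[[paste0("beta_", nm)]] *
          (baseline - centers[[nm]])
      # other covariates are held at their centers (contribution zero)
    }
    -emax_b * times / (et50 + times)
  })
  curves <- matrix(curves, nrow = length(times))
  qs <- apply(curves, 1, quantile, probs = c(0.5, 0.025, 0.975), names = FALSE)
  structure(list(band = data.frame(time_weeks = times,
                                   median = qs[1, ],
                                   lo95 = qs[2, ], hi95 = qs[3, ]),
                 baseline = baseline, n_draws = as.integer(n_draws)),
            class = "typical_band")
}

#' @export
print.typical_band <- function(x, ...) {
  cat(sprintf("Typical placebo response band at baseline ESSDAI %.1f (%d draws)\n",
              x$baseline, x$n_draws))
  print(transform(x$band, median = round(median, 2), lo95 = round(lo95, 2),
                  hi95 = round(hi95, 2)), row.names = FALSE)
  invisible(x)
}

#' Table-shaped typical-response report
#'
#' Long-format grid report (one row per baseline-time pair) of the
#' deterministic typical response, rounded to 2 decimals for
#' presentation; suitable for CSV export and surface plotting.
#'
#' @inheritParams typical_table
#' @param digits Rounding for the report (default 2).
#' @return Data frame `baseline, time_weeks, typical_change`.
#' @export
typical_report <- function(params, baselines, times, digits = 2) {
  m <- typical_table(params, baselines, times)
  data.frame(baseline = rep(baselines, times = length(times)),
             time_weeks = rep(times, each = length(baselines)),
             typical_change = round(as.numeric(m), digits))
}
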