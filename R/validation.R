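# Model qualification: goodness-of-fit quantities (PRED/IPRED/CWRES),
# leave-one-out (jackknife) sensitivity, visual predictive check, and
# sampling-importance-resampling parameter uncertainty.

#' Goodness-of-fit table (PRED, IPRED, CWRES)
#'
#' Per observation: the population prediction PRED (random effects at
#' zero), the individual prediction IPRED (at the empirical Bayes
#' estimates), and the conditional weighted residual CWRES. CWRES uses
#' the standard FOCE linearization about the EBEs: per trial the model
#' is linearized in eta at the posterior mode, giving marginal mean
#' `f(eta_hat) - F eta_hat` and covariance `F Omega F' + diag(sigma^2/N)`
#' with `F` the Jacobian of the mean curve in eta; the residual vector is
#' decorrelated by the inverse Cholesky factor of that covariance. With
#' both omegas zero CWRES reduces to `(obs - pred) * sqrt(N) / sigma`.
#'
#' @param fit A converged [fit_model()] result.
#' @param ds Dataset to diagnose (defaults to the fitted data).
#' @return Data frame with columns `trial_id`, `time_weeks`, `obs`,
#'   `pred`, `ipred`, `cwres`.
#' @export
gof_table <- function(fit, ds = fit$data) {
  stopifnot(inherits(fit, "placebo_fit"), inherits(ds, "meta_dataset"))
  if (!isTRUE(fit$converged)) stop("gof_table requires a converged fit")
  params <- fit$params
  ebes <- empirical_bayes(params, ds)
  sig2 <- params$sigma^2
  Om <- diag(c(params$omega_emax^2, params$omega_et50^2), 2)
  out <- lapply(seq_len(nrow(ds$covariates)), function(i) {
    id <- ds$covariates$trial_id[i]
    sel <- ds$observations$trial_id == id
    t <- ds$observations$time_weeks[sel]
    y <- ds$observations$change_essdai[sel]
    N <- ds$observations$n_subjects[sel]
    cov <- ds$covariates[i, , drop = FALSE]
    eta <- unlist(ebes[ebes$trial_id == id, c("eta_emax", "eta_et50")])
    base_emax <- trial_emax(params, cov, 0)
    pred <- predict_change(params, cov, list(eta_emax = 0, eta_et50 = 0), t)
    ipred <- predict_change(params, cov,
                            list(eta_emax = eta[1], eta_et50 = eta[2]), t)
    # Jacobian of f in eta at the EBEs
    cc <- .trial_curve(base_emax, params$theta_et50, t, eta[1], eta[2])
    Fj <- cbind(-cc$k, cc$E * cc$k * (1 - cc$k))
    V <- Fj %*% Om %*% t(Fj) + diag(sig2 / N, length(t))
    ch <- tryCatch(chol(.symm(V)), error = function(e)
      stop("singular marginal covariance for trial '", id, "'"))
    mu <- ipred - as.numeric(Fj %*% eta)
    cwres <- as.numeric(backsolve(ch, y - mu, transpose = TRUE))
    data.frame(trial_id = id, time_weeks = t, obs = y,
               pred = pred, ipred = ipred, cwres = cwres)
  })
  do.call(rbind, out)
}

#' Leave-one-out (jackknife) sensitivity analysis
#'
#' Refits the model once per omitted trial and reports every refit's
#' parameter estimates next to the all-data fit, with relative
#' deviations. Used qualitatively: a trial whose omission moves a
#' parameter far indicates undue influence.
#'
#' @param ds A prepared [meta_dataset()] with at least 3 trials.
#' @param covariates Covariate specification passed to [fit_model()].
#' @param config A [fit_config()].
#' @return Data frame, one row per omitted trial, with the refitted
#'   natural-scale parameters, `converged` flag, and `max_rel_dev` (the
#'   largest absolute relative deviation from the full fit across
#'   parameters). The full fit is attached as attribute `"full_fit"`.
#' @export
leave_one_out <- function(ds, covariates = character(), config = fit_config()) {
  stopifnot(inherits(ds, "meta_dataset"))
  if (n_trials(ds) < 3L) stop("leave-one-out needs at least 3 trials")
  full <- fit_model(ds, covariates, config)
  nat <- function(f) {
    p <- f$params
    c(theta_emax = p$theta_emax, theta_et50 = p$theta_et50,
      if (length(covariates))
        setNames(vapply(p$covariate_effects, function(e) e[["coef"]], numeric(1)),
                 paste0("beta_", names(p$covariate_effects))),
      omega_emax = p$omega_emax, omega_et50 = p$omega_et50, sigma = p$sigma)
  }
  ref <- nat(full)
  rows <- lapply(ds$covariates$trial_id, function(id) {
    keep_obs <- ds$observations$trial_id != id
    keep_cov <- ds$covariates$trial_id != id
    sub <- meta_dataset(ds$observations[keep_obs, ], ds$covariates[keep_cov, ],
                        provenance = paste("jackknife: omitted", id))
    f <- tryCatch(fit_model(sub, covariates, config), error = function(e) NULL)
    if (is.null(f) || !isTRUE(f$converged)) {
      est <- setNames(rep(NA_real_, length(ref)), names(ref))
      return(cbind(data.frame(omitted = id, converged = FALSE),
                   as.data.frame(as.list(est)),
                   max_rel_dev = NA_real_))
    }
    est <- nat(f)
    cbind(data.frame(omitted = id, converged = TRUE),
          as.data.frame(as.list(est)),
          max_rel_dev = max(abs((est - ref) / ref)))
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "full_fit") <- full
  out
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets at the estimates with the
#' original design (visit weeks, sample sizes, covariates), then per
#' nominal visit week pools the simulated changes across trials and
#' reports their 2.5/50/97.5 percentiles, with the observed values
#' attached for overlay. Bins are the nominal visit weeks themselves
#' (no smoothing): the corpus shares a sparse common grid.
#'
#' @param fit A converged [fit_model()] result.
#' @param ds Dataset supplying the design and observations (defaults to
#'   the fitted data).
#' @param n_sim Number of Monte-Carlo replicates (default 1000).
#' @param seed Integer seed; identical seeds give identical results.
#' @return Object of class `vpc_result`: list with `bands` (data frame
#'   `time_weeks, n_obs, p2.5, p50, p97.5`), `observed` (data frame
#'   `time_weeks, obs`), `n_sim`, `n_inside` and `coverage` (fraction of
#'   observations inside the 2.5-97.5 band).
#' @export
vpc <- function(fit, ds = fit$data, n_sim = 1000L, seed = 1L) {
  stopifnot(inherits(fit, "placebo_fit"), inherits(ds, "meta_dataset"),
            n_sim >= 1)
  if (!isTRUE(fit$converged)) stop("vpc requires a converged fit")
  params <- fit$params
  obs <- ds$observations
  design_cov <- ds$covariates
  times <- sort(unique(obs$time_weeks))
  sims_by_bin <- setNames(vector("list", length(times)), as.character(times))
  withr_seed(seed, {
    for (s in seq_len(n_sim)) {
      for (i in seq_len(nrow(design_cov))) {
        id <- design_cov$trial_id[i]
        sel <- obs$trial_id == id
        t <- obs$time_weeks[sel]; N <- obs$n_subjects[sel]
        e1 <- rnorm(1, 0, params$omega_emax)
        e2 <- rnorm(1, 0, params$omega_et50)
        f <- predict_change(params, design_cov[i, , drop = FALSE],
                            list(eta_emax = e1, eta_et50 = e2), t)
        ysim <- f + rnorm(length(t), 0, params$sigma / sqrt(N))
        for (j in seq_along(t)) {
          key <- as.character(t[j])
          sims_by_bin[[key]] <- c(sims_by_bin[[key]], ysim[j])
        }
      }
    }
  })
  bands <- do.call(rbind, lapply(times, function(tt) {
    v <- sims_by_bin[[as.character(tt)]]
    q <- quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(time_weeks = tt, n_obs = sum(obs$time_weeks == tt),
               `p2.5` = q[1], p50 = q[2], `p97.5` = q[3], check.names = FALSE)
  }))
  lo <- bands$`p2.5`[match(obs$time_weeks, bands$time_weeks)]
  hi <- bands$`p97.5`[match(obs$time_weeks, bands$time_weeks)]
  inside <- obs$change_essdai >= lo & obs$change_essdai <= hi
  structure(list(bands = bands,
                 observed = data.frame(time_weeks = obs$time_weeks,
                                       obs = obs$change_essdai,
                                       inside = inside),
                 n_sim = as.integer(n_sim),
                 n_inside = sum(inside),
                 coverage = mean(inside)),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("Visual predictive check: %d simulations, %d bins\n",
              x$n_sim, nrow(x$bands)))
  cat(sprintf("  %d/%d observations inside the 2.5-97.5%% band (%.1f%%)\n",
              x$n_inside, nrow(x$observed), 100 * x$coverage))
  print(x$bands, row.names = FALSE)
  invisible(x)
}

#' Parameter uncertainty by sampling importance resampling
#'
#' Draws `n_proposal` parameter vectors from a multivariate-normal
#' proposal centered at the estimates (transformed scale) with the
#' fit covariance inflated by `inflation`, weights each draw by
#' `exp(-(OFV - OFV_min)/2)` divided by the proposal density, and
#' resamples `n_resample` draws without replacement with probability
#' proportional to the weights. Reported per parameter (natural scale):
#' median and 2.5/97.5 percentiles of the resampled values.
#'
#' @param fit A converged [fit_model()] result with a valid covariance.
#' @param ds Dataset defining the OFV (defaults to the fitted data);
#'   ignored when `ofv_fn` is given.
#' @param n_proposal Proposal sample size (default 5000).
#' @param n_resample Resample size (default 1000; must not exceed
#'   `n_proposal`).
#' @param inflation Multiplier on the proposal covariance (default 1.5).
#' @param seed Integer seed.
#' @param sd_cap Upper bound on the per-parameter proposal SD
#'   (transformed scale, default 2). A parameter estimated at or near a
#'   boundary (an omega collapsing to zero) leaves the OFV flat in its
#'   direction and the covariance unbounded there; capping the proposal
#'   keeps the importance weights usable while still spanning any
#'   plausible value. Correlations are preserved.
#' @param ofv_fn Optional function of the transformed parameter vector
#'   returning the OFV; overrides the dataset-based OFV (used e.g. to
#'   check the method on an analytic surface).
#' @return Object of class `sir_result`: list with `summary` (data frame
#'   `parameter, median, lo95, hi95`), `ess` (effective sample size),
#'   `n_proposal`, `n_resample`, and `draws` (resampled natural-scale
#'   matrix).
#' @export
sir <- function(fit, ds = fit$data, n_proposal = 5000L, n_resample = 1000L,
                inflation = 1.5, seed = 1L, sd_cap = 2, ofv_fn = NULL) {
  stopifnot(inherits(fit, "placebo_fit"))
  if (n_resample > n_proposal)
    stop("n_resample must not exceed n_proposal")
  if (is.null(fit$covariance))
    stop("sir requires a fit with a valid covariance")
  if (!isTRUE(fit$converged)) stop("sir requires a converged fit")
  mu <- fit$coef
  Sig <- inflation * .symm(fit$covariance)
  sds <- sqrt(diag(Sig))
  shrink <- pmin(1, sd_cap / sds)
  Sig <- Sig * outer(shrink, shrink)
  if (is.null(ofv_fn)) {
    covariates <- fit$covariates; centers <- fit$centers
    blocks <- .trial_blocks(ds)
    Xc <- .cov_matrix(ds, covariates, centers)
    np <- length(covariates)
    ofv_fn <- function(par) {
      base <- rep(par[1], length(blocks)) +
        if (np) as.numeric(Xc %*% par[2 + seq_len(np)]) else 0
      .ofv_core(base, exp(par[2]), exp(par[3 + np]), exp(par[4 + np]),
                exp(par[5 + np]), blocks)
    }
  }
  p <- length(mu)
  withr_seed(seed, {
    draws <- MASS::mvrnorm(n_proposal, mu, Sig)
    if (is.null(dim(draws))) draws <- matrix(draws, ncol = p)
    ofvs <- apply(draws, 1, function(par) {
      v <- tryCatch(ofv_fn(par), error = function(e) Inf)
      if (!is.finite(v)) Inf else v
    })
    log_q <- .dmvnorm_log(draws, mu, Sig)
    log_w <- -(ofvs - min(ofvs)) / 2 - log_q
    log_w <- log_w - max(log_w[is.finite(log_w)])
    w <- exp(log_w); w[!is.finite(w)] <- 0
    w <- w / sum(w)
    ess <- 1 / sum(w^2)
    if (ess < 50)
      stop(sprintf(paste("degenerate importance weights (ESS = %.1f < 50);",
                         "increase the proposal inflation factor"), ess))
    idx <- sample.int(n_proposal, n_resample, replace = FALSE, prob = w)
    res <- draws[idx, , drop = FALSE]
  })
  # back-transform the log-scale parameters to the natural scale
  pn <- names(mu)
  logged <- pn %in% c("theta_et50", "omega_emax", "omega_et50", "sigma")
  nat <- res
  nat[, logged] <- exp(res[, logged])
  colnames(nat) <- pn
  qs <- t(apply(nat, 2, quantile, probs = c(0.5, 0.025, 0.975), names = FALSE))
  structure(list(summary = data.frame(parameter = pn, median = qs[, 1],
                                      lo95 = qs[, 2], hi95 = qs[, 3],
                                      row.names = NULL),
                 ess = ess, n_proposal = as.integer(n_proposal),
                 n_resample = as.integer(n_resample),
                 inflation = inflation, draws = nat),
            class = "sir_result")
}

#' @export
print.sir_result <- function(x, ...) {
  cat(sprintf("SIR parameter uncertainty: %d proposals, %d resampled, ESS %.0f\n",
              x$n_proposal, x$n_resample, x$ess))
  tab <- x$summary
  tab$`median (95% CI)` <- sprintf("%.3g (%.3g, %.3g)", tab$median,
                                   tab$lo95, tab$hi95)
  print(tab[c("parameter", "median (95% CI)")], row.names = FALSE)
  invisible(x)
}
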