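# Marginal-likelihood machinery for the Emax time-course mixed model.
#
# Per trial i with observations (t_j, y_j, N_j), random effects
# eta = (eta1, eta2), Emax_i = base_i + eta1, ET50_i = et50 * exp(eta2):
#
#   -2 log p(y_i, eta) = const + m(eta),
#   m(eta) = sum_j N_j (y_j - f_j(eta))^2 / sigma^2
#            + eta1^2/omega1^2 + eta2^2/omega2^2
#
# The marginal OFV contribution (n_obs*log(2*pi) dropped by convention,
# so only OFV differences are meaningful, as for the chi-square cutoffs) is
#
#   OFV_i = sum_j log(sigma^2/N_j) + sum_active log(omega_k^2)
#           + d*log(2*pi) - 2 log \int exp(-m(eta)/2) d eta
#
# evaluated either by Laplace at the mode of m (equivalently 1-node
# adaptive Gauss-Hermite) or by adaptive Gauss-Hermite quadrature with
# nodes >= 1 (the brute-force oracle). A random effect with omega = 0 is
# fixed at zero and drops out of the integral; with both omegas zero the
# OFV is the closed-form weighted least-squares deviance.

.PENALTY_OFV <- 1e10

# mean curve and eta-derivatives for one trial at eta = (e1, e2)
.trial_curve <- function(base_emax, et50, t, e1, e2) {
  E <- base_emax + e1
  k <- t / (et50 * exp(e2) + t)
  list(E = E, k = k, f = -E * k)
}

# m(eta), gradient and Hessian over the active dimensions
.m_eval <- function(eta, base_emax, et50, t, y, N, om1, om2, sig2,
                    active, want_deriv = TRUE) {
  cc <- .trial_curve(base_emax, et50, t, eta[1], eta[2])
  r <- y - cc$f
  w <- N / sig2
  pen <- (if (active[1]) eta[1]^2 / om1^2 else 0) +
         (if (active[2]) eta[2]^2 / om2^2 else 0)
  m <- sum(w * r^2) + pen
  if (!want_deriv) return(list(m = m))
  k <- cc$k
  df1 <- -k
  df2 <- cc$E * k * (1 - k)
  f12 <- k * (1 - k)
  f22 <- -cc$E * k * (1 - k) * (1 - 2 * k)
  g <- c(-2 * sum(w * r * df1) + if (active[1]) 2 * eta[1] / om1^2 else 0,
         -2 * sum(w * r * df2) + if (active[2]) 2 * eta[2] / om2^2 else 0)
  H <- matrix(0, 2, 2)
  H[1, 1] <- 2 * sum(w * df1^2) + if (active[1]) 2 / om1^2 else 0
  H[1, 2] <- H[2, 1] <- 2 * sum(w * (df1 * df2 - r * f12))
  H[2, 2] <- 2 * sum(w * (df2^2 - r * f22)) + if (active[2]) 2 / om2^2 else 0
  # Gauss-Newton part, always positive definite; fallback when H is not
  Hgn <- matrix(0, 2, 2)
  Hgn[1, 1] <- H[1, 1]
  Hgn[1, 2] <- Hgn[2, 1] <- 2 * sum(w * df1 * df2)
  Hgn[2, 2] <- 2 * sum(w * df2^2) + if (active[2]) 2 / om2^2 else 0
  list(m = m, g = g, H = H, Hgn = Hgn)
}

# profiled starting point: m is exactly quadratic in eta1 (the mean curve
# is linear in eta1), so for any eta2 the optimal eta1 is closed-form;
# a deterministic coarse grid over eta2 followed by Newton refinement
# avoids local-mode hysteresis in the marginal objective
.profile_start <- function(base_emax, et50, t, y, N, om1, om2, sig2, active) {
  w <- N / sig2
  if (!active[2]) {
    k <- t / (et50 + t)
    e1 <- if (active[1])
      -sum(w * k * (y + base_emax * k)) / (sum(w * k^2) + 1 / om1^2) else 0
    return(c(e1, 0))
  }
  L <- max(1, 5 * om2)
  g <- seq(-L, L, length.out = 21L)
  K <- outer(t, et50 * exp(g), function(tt, ee) tt / (ee + tt))  # n_obs x G
  wK <- w * K
  kk <- colSums(K * wK)
  e1 <- if (active[1])
    -(colSums(wK * y) + base_emax * kk) / (kk + 1 / om1^2)
  else rep(0, length(g))
  R <- y + K * rep(base_emax + e1, each = length(t))
  m <- colSums(w * R^2) + (if (active[1]) e1^2 / om1^2 else 0) + g^2 / om2^2
  j <- which.min(m)
  c(e1[j], g[j])
}

# minimization of m(eta) over the active dimensions: deterministic
# profiled start, then damped Newton
.inner_mode <- function(base_emax, et50, t, y, N, om1, om2, sig2,
                        eta0 = c(0, 0), tol = 1e-8, maxit = 60L) {
  active <- c(om1 > 0, om2 > 0)
  d <- sum(active)
  if (d == 0L) {
    ev <- .m_eval(c(0, 0), base_emax, et50, t, y, N, om1, om2, sig2,
                  active, want_deriv = FALSE)
    return(list(eta = c(0, 0), m = ev$m, H = NULL, active = active, ok = TRUE))
  }
  eta <- .profile_start(base_emax, et50, t, y, N, om1, om2, sig2, active)
  eta <- ifelse(active, eta, 0)
  ev <- .m_eval(eta, base_emax, et50, t, y, N, om1, om2, sig2, active)
  if (!is.finite(ev$m)) { eta <- c(0, 0); ev <- .m_eval(eta, base_emax, et50, t, y, N, om1, om2, sig2, active) }
  for (it in seq_len(maxit)) {
    g <- ev$g[active]
    if (max(abs(g)) < tol * (1 + abs(ev$m))) break
    Ha <- ev$H[active, active, drop = FALSE]
    usable <- all(is.finite(Ha)) &&
      (d == 1L && Ha[1, 1] > 0 ||
       d == 2L && Ha[1, 1] > 0 && det(Ha) > 0)
    if (!usable) Ha <- ev$Hgn[active, active, drop = FALSE]
    step <- tryCatch(-solve(Ha, g), error = function(e) -g / max(abs(diag(Ha)), 1))
    lam <- 1
    for (h in 1:25) {
      eta_new <- eta
      eta_new[active] <- eta[active] + lam * step
      ev_new <- .m_eval(eta_new, base_emax, et50, t, y, N, om1, om2, sig2, active)
      if (is.finite(ev_new$m) && ev_new$m <= ev$m + 1e-12) break
      lam <- lam / 2
    }
    if (!is.finite(ev_new$m) || ev_new$m > ev$m) break
    moved <- max(abs(eta_new - eta))
    eta <- eta_new; ev <- ev_new
    if (moved < 1e-12) break
  }
  H <- ev$H[active, active, drop = FALSE]
  pd <- all(is.finite(H)) && (d == 1L && H[1, 1] > 0 ||
                              d == 2L && H[1, 1] > 0 && det(H) > 0)
  if (!pd) H <- ev$Hgn[active, active, drop = FALSE]
  list(eta = eta, m = ev$m, H = H, active = active,
       ok = all(is.finite(eta)) && all(is.finite(H)))
}

# per-trial OFV contribution; nodes = 1 is exactly the Laplace value
.trial_ofv <- function(base_emax, et50, t, y, N, om1, om2, sig2,
                       nodes = 1L, eta0 = c(0, 0), inner_tol = 1e-8) {
  mode <- .inner_mode(base_emax, et50, t, y, N, om1, om2, sig2, eta0,
                      tol = inner_tol)
  if (!mode$ok || !is.finite(mode$m)) return(list(ofv = .PENALTY_OFV, eta = c(0, 0)))
  const <- sum(log(sig2 / N))
  d <- sum(mode$active)
  if (d == 0L) return(list(ofv = const + mode$m, eta = mode$eta))
  log_om2 <- sum(log(c(om1^2, om2^2)[mode$active]))
  A <- .symm(mode$H / 2)           # Hessian of m/2 at the mode
  if (nodes == 1L) {
    logdet <- determinant(A, logarithm = TRUE)
    if (logdet$sign <= 0) return(list(ofv = .PENALTY_OFV, eta = mode$eta))
    ofv <- const + log_om2 + mode$m + as.numeric(logdet$modulus)
    return(list(ofv = ofv, eta = mode$eta))
  }
  # adaptive Gauss-Hermite: eta = mode + sqrt(2) L x, L = lower chol of A^-1
  Sig <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Sig)) return(list(ofv = .PENALTY_OFV, eta = mode$eta))
  L <- t(chol(.symm(Sig)))
  gh <- pracma::gaussHermite(nodes)
  if (d == 1L) {
    xs <- matrix(gh$x, ncol = 1); lw <- log(gh$w)
  } else {
    grid <- expand.grid(a = seq_len(nodes), b = seq_len(nodes))
    xs <- cbind(gh$x[grid$a], gh$x[grid$b])
    lw <- log(gh$w[grid$a]) + log(gh$w[grid$b])
  }
  act <- which(mode$active)
  svals <- vapply(seq_len(nrow(xs)), function(g) {
    eta_g <- mode$eta
    eta_g[act] <- mode$eta[act] + sqrt(2) * as.numeric(L %*% xs[g, ])
    mg <- .m_eval(eta_g, base_emax, et50, t, y, N, om1, om2, sig2,
                  mode$active, want_deriv = FALSE)$m
    -mg / 2 + sum(xs[g, ]^2)
  }, numeric(1))
  Mx <- max(svals + lw)
  log_int <- (d / 2) * log(2) + sum(log(diag(L))) + Mx +
    log(sum(exp(svals + lw - Mx)))
  ofv <- const + log_om2 + d * log(2 * pi) - 2 * log_int
  list(ofv = ofv, eta = mode$eta)
}

# decompose a meta_dataset + parameters into per-trial fitting blocks
.trial_blocks <- function(ds, params = NULL) {
  ids <- ds$covariates$trial_id
  lapply(seq_along(ids), function(i) {
    sel <- ds$observations$trial_id == ids[i]
    list(id = ids[i],
         t = ds$observations$time_weeks[sel],
         y = ds$observations$change_essdai[sel],
         N = ds$observations$n_subjects[sel],
         cov = ds$covariates[i, , drop = FALSE])
  })
}

# core OFV over precomputed per-trial blocks, scalar parameters
.ofv_core <- function(base_vec, et50, om1, om2, sigma, blocks,
                      nodes = 1L, inner_tol = 1e-8) {
  sig2 <- sigma^2
  total <- 0
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    res <- .trial_ofv(base_vec[i], et50, b$t, b$y, b$N, om1, om2, sig2,
                      nodes = nodes, inner_tol = inner_tol)
    total <- total + res$ofv
  }
  total
}

# centered covariate design matrix (n_trials x p)
.cov_matrix <- function(ds, covariates, centers) {
  p <- length(covariates)
  if (!p) return(matrix(0, n_trials(ds), 0))
  m <- vapply(seq_len(p), function(j)
    ds$covariates[[covariates[j]]] - centers[[j]], numeric(n_trials(ds)))
  matrix(m, nrow = n_trials(ds))
}

.dataset_ofv <- function(params, ds, nodes = 1L, inner_tol = 1e-8,
                         blocks = NULL) {
  if (is.null(blocks)) blocks <- .trial_blocks(ds)
  base <- vapply(blocks, function(b) trial_emax(params, b$cov, 0), numeric(1))
  .ofv_core(base, params$theta_et50, params$omega_emax, params$omega_et50,
            params$sigma, blocks, nodes = nodes, inner_tol = inner_tol)
}

#' Objective function value by the Laplace approximation
#'
#' Minus twice the approximate log marginal likelihood of the dataset
#' under the mixed-effects Emax model, with the Laplace approximation
#' taken at the per-trial mode of the joint log-density. The additive
#' `n * log(2*pi)` constant is excluded, so only OFV differences are
#' meaningful — exactly what the chi-square covariate cutoffs use. With
#' both inter-trial SDs zero this reduces to the closed-form weighted
#' least-squares deviance
#' \eqn{\sum_{ij} [N_{ij}(y_{ij}-\hat y_{ij})^2/\sigma^2 +
#' \log(\sigma^2/N_{ij})]}.
#'
#' @param params [model_parameters()]; every covariate named there must
#'   be present (non-missing) in `ds`.
#' @param ds A [meta_dataset()].
#' @return The OFV (scalar). Parameter sets giving a non-finite density
#'   return a large penalty value.
#' @seealso [ofv_quadrature()] for the brute-force quadrature oracle.
#' @export
ofv_laplace <- function(params, ds) {
  stopifnot(inherits(params, "model_parameters"), inherits(ds, "meta_dataset"))
  if (params$sigma <= 0) stop("the OFV requires sigma > 0")
  .dataset_ofv(params, ds, nodes = 1L)
}

#' Objective function value by adaptive Gauss-Hermite quadrature
#'
#' Evaluates the per-trial marginal integrals over the random effects by
#' adaptive Gauss-Hermite quadrature centered and scaled at the joint
#' mode. With `nodes = 1` this is algebraically identical to
#' [ofv_laplace()]; with many nodes it serves as a brute-force accuracy
#' oracle for the Laplace approximation. Same additive-constant
#' convention as [ofv_laplace()].
#'
#' @inheritParams ofv_laplace
#' @param nodes Number of quadrature nodes per random-effect dimension
#'   (>= 1; >= 5 recommended for a meaningful oracle).
#' @return The OFV (scalar).
#' @export
ofv_quadrature <- function(params, ds, nodes = 9L) {
  stopifnot(inherits(params, "model_parameters"), inherits(ds, "meta_dataset"),
            is.numeric(nodes), nodes >= 1)
  if (params$sigma <= 0) stop("the OFV requires sigma > 0")
  .dataset_ofv(params, ds, nodes = as.integer(nodes))
}

#' Empirical Bayes estimates of the trial random effects
#'
#' Per-trial posterior modes of (eta_Emax, eta_ET50) at fixed model
#' parameters: the minimizers of the joint deviance m(eta). A random
#' effect whose omega is zero is fixed at 0 (full shrinkage); as omega
#' grows the estimates approach the values that interpolate the data
#' (no shrinkage).
#'
#' @inheritParams ofv_laplace
#' @return Data frame with columns `trial_id`, `eta_emax`, `eta_et50`.
#' @export
empirical_bayes <- function(params, ds) {
  stopifnot(inherits(params, "model_parameters"), inherits(ds, "meta_dataset"))
  blocks <- .trial_blocks(ds)
  sig2 <- params$sigma^2
  out <- lapply(blocks, function(b) {
    base_emax <- trial_emax(params, b$cov, 0)
    mode <- .inner_mode(base_emax, params$theta_et50, b$t, b$y, b$N,
                        params$omega_emax, params$omega_et50, sig2)
    if (!mode$ok) {
      warning("empirical Bayes optimization failed for trial '", b$id,
              "'; returning zeros")
      mode$eta <- c(0, 0)
    }
    data.frame(trial_id = b$id, eta_emax = mode$eta[1], eta_et50 = mode$eta[2])
  })
  do.call(rbind, out)
}

#' Fitting configuration
#'
#' @param initial Optional named list overriding the automatic starting
#'   values; any of `theta_emax`, `theta_et50`, `omega_emax`,
#'   `omega_et50`, `sigma`, or `beta` (named vector of covariate
#'   coefficients).
#' @param approx Likelihood approximation: `"laplace"` (default) or
#'   `"quadrature"`.
#' @param nodes Quadrature nodes per dimension when
#'   `approx = "quadrature"`.
#' @param inner_tol Convergence tolerance of the nested per-trial
#'   random-effect optimization.
#' @param outer_tol Relative tolerance of the outer parameter search.
#' @param max_iter Maximum outer iterations.
#' @param n_starts Number of optimizer starts (the first from the
#'   automatic/supplied initials, the rest jittered).
#' @param seed Seed for the multi-start jitter.
#' @param hessian Compute the finite-difference Hessian (and hence the
#'   covariance and RSEs) at the optimum. Intermediate fits of a
#'   covariate search switch this off; the final model keeps it on.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(initial = NULL, approx = c("laplace", "quadrature"),
                       nodes = 9L, inner_tol = 1e-8, outer_tol = 1e-6,
                       max_iter = 300L, n_starts = 1L, seed = 1L,
                       hessian = TRUE) {
  approx <- match.arg(approx)
  stopifnot(inner_tol > 0, outer_tol > 0, nodes >= 1, max_iter >= 1,
            n_starts >= 1)
  structure(list(initial = initial, approx = approx, nodes = as.integer(nodes),
                 inner_tol = inner_tol, outer_tol = outer_tol,
                 max_iter = as.integer(max_iter), n_starts = as.integer(n_starts),
                 seed = as.integer(seed), hessian = isTRUE(hessian)),
            class = "fit_config")
}

# transformed parameter vector <-> model_parameters
# layout: theta_emax, log(theta_et50), beta_<cov>..., log(om1), log(om2), log(sigma)
.par_names <- function(covariates) {
  c("theta_emax", "theta_et50",
    if (length(covariates)) paste0("beta_", covariates),
    "omega_emax", "omega_et50", "sigma")
}

.par_to_params <- function(par, covariates, centers) {
  p <- length(covariates)
  beta <- if (p) par[2 + seq_len(p)] else numeric()
  ce <- if (p) {
    eff <- lapply(seq_len(p), function(j)
      c(coef = unname(beta[j]), center = unname(centers[[covariates[j]]])))
    names(eff) <- covariates
    eff
  } else list()
  model_parameters(theta_emax = par[1], theta_et50 = exp(par[2]),
                   covariate_effects = ce,
                   omega_emax = exp(par[3 + p]), omega_et50 = exp(par[4 + p]),
                   sigma = exp(par[5 + p]))
}

.params_to_par <- function(params) {
  covs <- names(params$covariate_effects)
  beta <- vapply(params$covariate_effects, function(e) e[["coef"]], numeric(1))
  c(params$theta_emax, log(params$theta_et50), unname(beta),
    log(max(params$omega_emax, 1e-6)), log(max(params$omega_et50, 1e-6)),
    log(params$sigma))
}

# automatic starting values (see fit_model documentation)
.auto_init <- function(ds, covariates) {
  obs <- ds$observations
  last <- vapply(split(seq_len(nrow(obs)), obs$trial_id), function(i)
    obs$change_essdai[i[which.max(obs$time_weeks[i])]], numeric(1))
  th0 <- -mean(last)
  if (!is.finite(th0) || abs(th0) < 0.5) th0 <- sign(th0 + 1e-9) * 0.5
  maxfu <- vapply(split(obs$time_weeks, obs$trial_id), max, numeric(1))
  et50_0 <- max(1, median(maxfu) / 2)
  pred0 <- -th0 * obs$time_weeks / (et50_0 + obs$time_weeks)
  sig0 <- sd((obs$change_essdai - pred0) * sqrt(obs$n_subjects))
  if (!is.finite(sig0) || sig0 < 0.1) sig0 <- 0.1
  list(theta_emax = th0, theta_et50 = et50_0,
       beta = setNames(rep(0, length(covariates)), covariates),
       omega_emax = 0.3, omega_et50 = 0.3, sigma = sig0)
}

#' Fit the mixed-effects Emax placebo-response model
#'
#' Minimizes the Laplace (or quadrature) OFV over the fixed effects,
#' covariate coefficients, inter-trial SDs and residual SD, with
#' positivity enforced through log transforms of ET50, the omegas and
#' sigma. Continuous covariates enter Emax linearly, centered at their
#' across-trial median. Starting values default to: theta_Emax = minus
#' the mean last-visit change, theta_ET50 = half the median follow-up,
#' omegas 0.3, sigma from the naive-curve residuals; coefficients 0.
#' The parameter covariance comes from the inverse finite-difference
#' Hessian of OFV/2 at the optimum (transformed scale), with
#' delta-method back-transformation for the reported relative standard
#' errors.
#'
#' @param ds A [meta_dataset()] with no missing values in the requested
#'   covariates (run [prepare_covariates()] first).
#' @param covariates Character vector of covariate names to place on
#'   Emax (possibly empty for the base model).
#' @param config A [fit_config()].
#' @return An object of class `placebo_fit` with elements `params`
#'   (estimates as [model_parameters()]), `ofv`, `coef` (transformed
#'   scale), `covariance` (transformed scale), `se`, `rse_pct` (natural
#'   scale), `ebes`, `converged`, `n_obs`, `n_trials`, `centers`,
#'   `data`. Non-convergence is reported through `converged = FALSE`,
#'   not an error.
#' @export
fit_model <- function(ds, covariates = character(), config = fit_config()) {
  stopifnot(inherits(ds, "meta_dataset"), inherits(config, "fit_config"))
  covariates <- as.character(covariates)
  for (nm in covariates)
    if (!nm %in% names(ds$covariates) || any(is.na(ds$covariates[[nm]])))
      stop("covariate '", nm, "' absent or missing; run prepare_covariates() first")
  centers <- lapply(covariates, function(nm) median(ds$covariates[[nm]]))
  names(centers) <- covariates

  init <- .auto_init(ds, covariates)
  if (!is.null(config$initial))
    for (nm in names(config$initial)) init[[nm]] <- config$initial[[nm]]
  p <- length(covariates)
  par0 <- c(init$theta_emax, log(init$theta_et50),
            if (p) unname(init$beta[covariates]),
            log(init$omega_emax), log(init$omega_et50), log(init$sigma))

  nodes <- if (config$approx == "laplace") 1L else config$nodes
  blocks <- .trial_blocks(ds)
  Xc <- .cov_matrix(ds, covariates, centers)
  objective <- function(par) {
    if (any(!is.finite(par))) return(.PENALTY_OFV)
    base <- rep(par[1], length(blocks)) +
      if (p) as.numeric(Xc %*% par[2 + seq_len(p)]) else 0
    v <- .ofv_core(base, exp(par[2]), exp(par[3 + p]), exp(par[4 + p]),
                   exp(par[5 + p]), blocks, nodes = nodes,
                   inner_tol = config$inner_tol)
    if (!is.finite(v)) .PENALTY_OFV else v
  }
  # box constraints on the transformed scale
  lb <- c(-50, log(0.1), if (p) rep(-20, p), log(1e-4), log(1e-4), log(1e-3))
  ub <- c(50, log(500), if (p) rep(20, p), log(20), log(20), log(50))
  ctrl <- list(iter.max = config$max_iter, eval.max = 4L * config$max_iter,
               rel.tol = config$outer_tol)
  run_start <- function(s) {
    # gradient-based descent first; when nlminb cannot certify ("false
    # convergence", typically at the small kinks the Laplace objective
    # has where a trial's inner mode switches basins), polish with full
    # Nelder-Mead runs until one gains < 0.05 OFV, then re-certify
    opt <- tryCatch(nlminb(s, objective, lower = lb, upper = ub, control = ctrl),
                    error = function(e) NULL)
    if (is.null(opt))
      opt <- list(par = s, objective = objective(s), convergence = 1L,
                  message = "nlminb error")
    stationary <- opt$convergence == 0
    if (!stationary) {
      for (cycle in 1:6) {
        nm <- tryCatch(optim(opt$par, function(x) objective(pmin(pmax(x, lb), ub)),
                             method = "Nelder-Mead",
                             control = list(maxit = 5000, reltol = 1e-10)),
                       error = function(e) NULL)
        if (is.null(nm)) break
        gain <- opt$objective - nm$value
        if (nm$value < opt$objective) {
          opt$par <- pmin(pmax(nm$par, lb), ub)
          opt$objective <- objective(opt$par)
        }
        if (gain < 0.05) { stationary <- TRUE; break }
      }
      o2 <- tryCatch(nlminb(opt$par, objective, lower = lb, upper = ub,
                            control = ctrl), error = function(e) NULL)
      if (!is.null(o2) && o2$objective <= opt$objective) {
        stationary <- stationary || o2$convergence == 0
        opt$par <- o2$par; opt$objective <- o2$objective
        opt$message <- o2$message
      }
    }
    opt$stationary <- stationary
    opt
  }

  starts <- list(par0)
  if (config$n_starts > 1L)
    starts <- c(starts, withr_seed(config$seed, lapply(
      seq_len(config$n_starts - 1L),
      function(i) par0 + rnorm(length(par0), 0, 0.3))))
  best <- NULL
  for (s in starts) {
    opt <- run_start(s)
    if (is.null(opt)) next
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  pn <- .par_names(covariates)
  if (is.null(best)) {
    warning("all optimizer starts failed")
    params0 <- .par_to_params(par0, covariates, centers)
    return(structure(list(params = params0, ofv = NA_real_,
                          coef = setNames(par0, pn), covariance = NULL,
                          se = setNames(rep(NA_real_, length(pn)), pn),
                          rse_pct = setNames(rep(NA_real_, length(pn)), pn),
                          ebes = NULL, converged = FALSE,
                          n_obs = n_obs(ds), n_trials = n_trials(ds),
                          covariates = covariates, centers = centers,
                          config = config, data = ds),
                     class = "placebo_fit"))
  }
  par_hat <- best$par
  params <- .par_to_params(par_hat, covariates, centers)
  converged <- best$convergence == 0 || isTRUE(best$stationary)

  unc <- if (isTRUE(config$hessian))
    .uncertainty_from_hessian(objective, par_hat, params, p, pn)
  else list(covariance = NULL,
            se = setNames(rep(NA_real_, length(pn)), pn),
            rse_pct = setNames(rep(NA_real_, length(pn)), pn),
            note = "not computed")

  structure(list(params = params, ofv = best$objective,
                 coef = setNames(par_hat, pn), covariance = unc$covariance,
                 se = unc$se, rse_pct = unc$rse_pct,
                 ebes = empirical_bayes(params, ds),
                 converged = isTRUE(converged),
                 n_obs = n_obs(ds), n_trials = n_trials(ds),
                 covariates = covariates, centers = centers,
                 config = config, data = ds,
                 message = best$message, cov_note = unc$note),
            class = "placebo_fit")
}

# covariance of the transformed parameters: inverse FD Hessian of OFV/2;
# a non-positive-definite Hessian (flat omega direction, boundary
# optimum) falls back to an eigenvalue-clipped inverse so downstream
# uncertainty machinery stays usable, with the note recorded
.uncertainty_from_hessian <- function(objective, par_hat, params, p, pn) {
  H <- .fd_hessian(function(par) objective(par) / 2, par_hat, h = 1e-3)
  covariance <- tryCatch({
    V <- solve(.symm(H))
    if (any(!is.finite(V)) || any(diag(V) <= 0)) NULL else V
  }, error = function(e) NULL)
  note <- "inverse Hessian"
  if (is.null(covariance) && all(is.finite(H))) {
    ev <- eigen(.symm(H), symmetric = TRUE)
    lam <- pmax(ev$values, max(abs(ev$values)) * 1e-6)
    covariance <- ev$vectors %*% diag(1 / lam, length(lam)) %*% t(ev$vectors)
    note <- "eigenvalue-clipped inverse Hessian (non-PD at optimum)"
  }
  se_t <- if (!is.null(covariance)) sqrt(diag(covariance))
          else rep(NA_real_, length(par_hat))
  # natural-scale SE: identity for theta_emax and betas, delta method
  # (se * value) for the log-transformed parameters
  est_nat <- c(params$theta_emax, params$theta_et50,
               if (p) vapply(params$covariate_effects, function(e) e[["coef"]],
                             numeric(1)),
               params$omega_emax, params$omega_et50, params$sigma)
  logged <- c(FALSE, TRUE, rep(FALSE, p), TRUE, TRUE, TRUE)
  se_nat <- ifelse(logged, se_t * abs(est_nat), se_t)
  rse <- 100 * se_nat / abs(est_nat)
  if (!is.null(covariance)) dimnames(covariance) <- list(pn, pn)
  list(covariance = covariance, se = setNames(se_nat, pn),
       rse_pct = setNames(rse, pn), note = note)
}

# backfill covariance/SEs on a fit produced with hessian = FALSE
.add_covariance <- function(fit, ds) {
  if (!is.null(fit$covariance)) return(fit)
  covariates <- fit$covariates
  p <- length(covariates)
  blocks <- .trial_blocks(ds)
  Xc <- .cov_matrix(ds, covariates, fit$centers)
  objective <- function(par) {
    base <- rep(par[1], length(blocks)) +
      if (p) as.numeric(Xc %*% par[2 + seq_len(p)]) else 0
    v <- .ofv_core(base, exp(par[2]), exp(par[3 + p]), exp(par[4 + p]),
                   exp(par[5 + p]), blocks)
    if (!is.finite(v)) .PENALTY_OFV else v
  }
  unc <- .uncertainty_from_hessian(objective, fit$coef, fit$params, p,
                                   names(fit$coef))
  fit$covariance <- unc$covariance
  fit$se <- unc$se
  fit$rse_pct <- unc$rse_pct
  fit$cov_note <- unc$note
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# central finite-difference Hessian
.fd_hessian <- function(fn, x, h = 1e-3) {
  n <- length(x)
  hh <- h * (1 + abs(x))
  H <- matrix(NA_real_, n, n)
  f0 <- fn(x)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + hh[i]
        xm <- x; xm[i] <- x[i] - hh[i]
        H[i, i] <- (fn(xp) - 2 * f0 + fn(xm)) / hh[i]^2
      } else {
        xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + hh[c(i, j)]
        xpm <- x; xpm[i] <- x[i] + hh[i]; xpm[j] <- x[j] - hh[j]
        xmp <- x; xmp[i] <- x[i] - hh[i]; xmp[j] <- x[j] + hh[j]
        xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - hh[c(i, j)]
        H[i, j] <- H[j, i] <-
          (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * hh[i] * hh[j])
      }
    }
  }
  H
}

#' @export
print.placebo_fit <- function(x, ...) {
  cat("Mixed-effects Emax placebo-response model fit\n")
  cat(sprintf("  %d trials, %d observations; OFV = %.3f; converged: %s\n\n",
              x$n_trials, x$n_obs, x$ofv, x$converged))
  est <- c(x$params$theta_emax, x$params$theta_et50,
           vapply(x$params$covariate_effects, function(e) e[["coef"]], numeric(1)),
           x$params$omega_emax, x$params$omega_et50, x$params$sigma)
  lab <- c("Emax (score)", "ET50 (week)",
           if (length(x$covariates)) paste0("theta(", x$covariates, ") on Emax"),
           "eta Emax (SD)", "eta ET50 (SD)", "epsilon (SD)")
  tab <- data.frame(Parameter = lab,
                    Value = signif(est, 3),
                    `RSE (%)` = round(unname(x$rse_pct), 1),
                    check.names = FALSE)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Serialize a fit to JSON (Table-2-style report)
#'
#' @param fit A [fit_model()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "placebo_fit"))
  x <- list(
    parameters = list(
      theta_emax = fit$params$theta_emax, theta_et50 = fit$params$theta_et50,
      covariate_effects = lapply(fit$params$covariate_effects, as.list),
      omega_emax = fit$params$omega_emax, omega_et50 = fit$params$omega_et50,
      sigma = fit$params$sigma),
    rse_pct = as.list(fit$rse_pct),
    ofv = fit$ofv, converged = fit$converged,
    n_obs = fit$n_obs, n_trials = fit$n_trials,
    covariates = fit$covariates,
    ebes = fit$ebes)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
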