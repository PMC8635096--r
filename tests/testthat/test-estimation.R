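p2 <- table2_params()

test_that("with no inter-trial variability the OFV is the closed-form weighted deviance", {
  ds <- toy_dataset(n_trials = 4, seed = 71)
  p0 <- model_parameters(4.0, 10, omega_emax = 0, omega_et50 = 0, sigma = 1.3)
  byhand <- 0
  for (i in seq_len(n_trials(ds))) {
    id <- ds$covariates$trial_id[i]
    sel <- ds$observations$trial_id == id
    f <- predict_change(p0, ds$covariates[i, ], time =
                          ds$observations$time_weeks[sel])
    y <- ds$observations$change_essdai[sel]
    N <- ds$observations$n_subjects[sel]
    byhand <- byhand + sum((y - f)^2 * N / 1.3^2 + log(1.3^2 / N))
  }
  expect_equal(ofv_laplace(p0, ds), byhand, tolerance = 1e-10)
  expect_equal(ofv_quadrature(p0, ds, nodes = 7), byhand, tolerance = 1e-10)
})

test_that("doubling sigma on perfectly fitted data raises the OFV by n * 2 log 2", {
  ds <- noise_free_dataset()
  p_a <- model_parameters(4.44, 12.2, covariate_effects = p2$covariate_effects,
                          omega_emax = 0, omega_et50 = 0, sigma = 1)
  p_b <- model_parameters(4.44, 12.2, covariate_effects = p2$covariate_effects,
                          omega_emax = 0, omega_et50 = 0, sigma = 2)
  expect_equal(ofv_laplace(p_b, ds) - ofv_laplace(p_a, ds),
               n_obs(ds) * 2 * log(2), tolerance = 1e-10)
})

test_that("Laplace equals one-node adaptive quadrature exactly, and many nodes agree", {
  for (seed in c(11, 12, 13)) {
    ds <- toy_dataset(n_trials = 3, seed = seed)
    expect_equal(ofv_laplace(p2, ds), ofv_quadrature(p2, ds, nodes = 1),
                 tolerance = 1e-12)
    # mixed case: one random effect switched off
    pmix <- model_parameters(4.44, 12.2,
                             covariate_effects = p2$covariate_effects,
                             omega_emax = 0, omega_et50 = 0.5, sigma = 1.661)
    expect_equal(ofv_laplace(pmix, ds), ofv_quadrature(pmix, ds, nodes = 1),
                 tolerance = 1e-12)
  }
})

test_that("quadrature converges monotonically in the node count", {
  pmod <- model_parameters(4.44, 12.2, covariate_effects = p2$covariate_effects,
                           omega_emax = 0.3, omega_et50 = 0.3, sigma = 1.661)
  ds <- toy_dataset(n_trials = 3, seed = 21, params = pmod)
  ref <- ofv_quadrature(pmod, ds, nodes = 21)
  gaps <- vapply(c(5, 9, 15), function(k)
    abs(ofv_quadrature(pmod, ds, nodes = k) - ref), numeric(1))
  expect_true(all(diff(gaps) <= 1e-12))
  expect_lt(gaps[3], 1e-4)
})

test_that("the OFV is invariant to trial order and relabeling", {
  ds <- toy_dataset(n_trials = 5, seed = 41)
  v0 <- ofv_laplace(p2, ds)
  perm <- c(3, 1, 5, 2, 4)
  cov_p <- ds$covariates[perm, ]
  obs_p <- ds$observations[order(match(ds$observations$trial_id,
                                       cov_p$trial_id)), ]
  ds_p <- meta_dataset(obs_p, cov_p)
  expect_equal(ofv_laplace(p2, ds_p), v0, tolerance = 1e-9)
  relab <- setNames(sprintf("Z%d", 1:5), ds$covariates$trial_id)
  obs_r <- ds$observations; obs_r$trial_id <- unname(relab[obs_r$trial_id])
  cov_r <- ds$covariates; cov_r$trial_id <- unname(relab[cov_r$trial_id])
  expect_equal(ofv_laplace(p2, meta_dataset(obs_r, cov_r)), v0,
               tolerance = 1e-9)
})

test_that("empirical Bayes estimates shrink correctly in the omega limits", {
  ds <- noise_free_dataset()
  # data exactly on the typical curve: modes at zero
  pmod <- model_parameters(4.44, 12.2, covariate_effects = p2$covariate_effects,
                           omega_emax = 0.5, omega_et50 = 0.5, sigma = 1)
  eb <- empirical_bayes(pmod, ds)
  expect_equal(eb$eta_emax, rep(0, 3), tolerance = 1e-6)
  expect_equal(eb$eta_et50, rep(0, 3), tolerance = 1e-6)
  # omega -> 0 forces full shrinkage whatever the data
  ds2 <- toy_dataset(n_trials = 3, seed = 61)
  p0 <- model_parameters(4.44, 12.2, omega_emax = 0, omega_et50 = 0,
                         sigma = 1.661)
  eb0 <- empirical_bayes(p0, ds2)
  expect_true(all(eb0$eta_emax == 0 & eb0$eta_et50 == 0))
  # a single observation with a diffuse Emax effect is interpolated
  d1 <- one_trial_design(times = 24, n = 25L, baseline = 10.1)
  p1 <- model_parameters(4.44, 12.2, omega_emax = 50, omega_et50 = 0,
                         sigma = 1.661)
  ds1 <- simulate_dataset(d1, p1, seed = 8)
  eb1 <- empirical_bayes(p1, ds1)
  ipred <- predict_change(p1, ds1$covariates[1, ],
                          list(eta_emax = eb1$eta_emax, eta_et50 = 0), 24)
  expect_lt(abs(ipred - ds1$observations$change_essdai), 5e-3)
})

test_that("estimates recover the truth on an informative corpus", {
  p_true <- model_parameters(4.44, 12.2,
    covariate_effects = list(baseline_essdai = c(coef = 0.552, center = 10.1)),
    omega_emax = 0.01, omega_et50 = 0.01, sigma = 0.3)
  d <- sample_design(40, seed = 11)
  ds <- simulate_dataset(d, p_true, seed = 12)
  f <- fit_model(ds, "baseline_essdai")
  expect_true(f$converged)
  emax_ref <- trial_emax(f$params, list(baseline_essdai = 10.1))
  expect_equal(emax_ref, 4.44, tolerance = 0.1 * 4.44)
  expect_equal(f$params$theta_et50, 12.2, tolerance = 0.1 * 12.2)
  expect_equal(f$params$covariate_effects$baseline_essdai[["coef"]], 0.552,
               tolerance = 0.1)
  # the reported uncertainty is usable
  expect_false(is.null(f$covariance))
  expect_true(all(is.finite(f$rse_pct)))
})

test_that("the optimum is a fixed point and robust to the starting values", {
  ds <- toy_dataset(n_trials = 6, seed = 81)
  f1 <- fit_model(ds, character())
  expect_true(f1$converged)
  restart <- fit_config(initial = list(
    theta_emax = f1$params$theta_emax, theta_et50 = f1$params$theta_et50,
    omega_emax = max(f1$params$omega_emax, 1e-3),
    omega_et50 = max(f1$params$omega_et50, 1e-3),
    sigma = f1$params$sigma), hessian = FALSE)
  f2 <- fit_model(ds, character(), restart)
  expect_lt(f1$ofv - f2$ofv, 0.01)
  other <- fit_config(initial = list(theta_emax = 1.5, theta_et50 = 25,
                                     omega_emax = 0.8, omega_et50 = 0.8,
                                     sigma = 2.5), hessian = FALSE)
  f3 <- fit_model(ds, character(), other)
  expect_equal(f3$ofv, f2$ofv, tolerance = 0.1)
})
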