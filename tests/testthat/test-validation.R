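p2 <- table2_params()

test_that("CWRES reduces to the weighted residual when omegas are zero", {
  ds <- toy_dataset(n_trials = 4, seed = 14)
  p0 <- model_parameters(4.44, 12.2, covariate_effects = p2$covariate_effects,
                         omega_emax = 0, omega_et50 = 0, sigma = 1.661)
  g <- gof_table(fake_fit(p0, ds), ds)
  expect_equal(g$cwres, (g$obs - g$pred) * sqrt(
    ds$observations$n_subjects) / 1.661, tolerance = 1e-10)
  expect_equal(g$ipred, g$pred)  # no random effects, no individualization
  # perfectly fitted data: all residuals zero
  ds0 <- noise_free_dataset()
  p0s <- model_parameters(4.44, 12.2, covariate_effects = p2$covariate_effects,
                          omega_emax = 0, omega_et50 = 0, sigma = 1)
  g0 <- gof_table(fake_fit(p0s, ds0), ds0)
  expect_equal(g0$cwres, rep(0, nrow(g0)))
})

test_that("CWRES is calibrated under the generating model", {
  nt <- 150
  trs <- data.frame(trial_id = sprintf("T%03d", 1:nt), n_subjects = 30L,
                    duration_weeks = 48,
                    baseline_essdai = seq(3, 13, length.out = nt),
                    age_years = 54.4, male_pct = 5, diagnosis_years = 5.3,
                    base_therapy_pct = 78.5)
  des <- manual_design(trs, setNames(rep(list(c(8, 16, 24, 48)), nt),
                                     trs$trial_id))
  ds <- simulate_dataset(des, p2, seed = 77)
  g <- gof_table(fake_fit(p2, ds), ds)
  expect_lt(abs(mean(g$cwres)), 0.1)
  expect_gt(sd(g$cwres), 0.85)
  expect_lt(sd(g$cwres), 1.15)
})

test_that("leave-one-out needs 3 trials and is exchangeable on identical trials", {
  obs1 <- data.frame(trial_id = "A", time_weeks = c(8, 16, 24),
                     change_essdai = c(-1.1, -1.8, -2.2), n_subjects = 30L)
  mk <- function(ids) {
    obs <- do.call(rbind, lapply(ids, function(id)
      transform(obs1, trial_id = id)))
    cov <- data.frame(trial_id = ids, baseline_essdai = 9.5,
                      age_years = 54.4, male_pct = 5, duration_weeks = 24,
                      diagnosis_years = 5.3, base_therapy_pct = 78.5)
    meta_dataset(obs, cov)
  }
  expect_error(leave_one_out(mk(c("A", "B"))), "at least 3 trials")
  cfg <- fit_config(hessian = FALSE)
  jk <- leave_one_out(mk(c("A", "B", "C", "D")), config = cfg)
  expect_equal(nrow(jk), 4L)
  expect_true(all(jk$converged))
  # omitting any copy of the same trial leaves the identified parameters
  # untouched (the omegas sit at the zero boundary here, where relative
  # comparisons are meaningless)
  for (col in c("theta_emax", "theta_et50", "sigma"))
    expect_lt(diff(range(jk[[col]])), 0.02 * abs(mean(jk[[col]])))
})

test_that("VPC bands are seed-stable, nested, and collapse without variability", {
  ds <- toy_dataset(n_trials = 5, seed = 44)
  f <- fake_fit(p2, ds)
  v1 <- vpc(f, ds, n_sim = 200, seed = 9)
  v2 <- vpc(f, ds, n_sim = 200, seed = 9)
  expect_identical(v1$bands, v2$bands)
  expect_true(all(v1$bands$`p2.5` <= v1$bands$p50 &
                  v1$bands$p50 <= v1$bands$`p97.5`))
  # degenerate model: the band is the typical curve with zero width
  # (trials share one baseline so each nominal-time bin is a single value)
  p0 <- model_parameters(4.44, 12.2, covariate_effects = p2$covariate_effects,
                         omega_emax = 0, omega_et50 = 0, sigma = 0)
  ds0 <- noise_free_dataset(baselines = c(9, 9, 9))
  v0 <- vpc(fake_fit(p0, ds0), ds0, n_sim = 50, seed = 1)
  expect_equal(v0$bands$`p2.5`, v0$bands$`p97.5`)
  expect_equal(v0$coverage, 1)
  # widening the variability never narrows a band
  pwide <- model_parameters(4.44, 12.2,
                            covariate_effects = p2$covariate_effects,
                            omega_emax = 1.2, omega_et50 = 1.2, sigma = 3)
  vw <- vpc(fake_fit(pwide, ds), ds, n_sim = 200, seed = 9)
  expect_true(all(vw$bands$`p97.5` - vw$bands$`p2.5` >=
                  v1$bands$`p97.5` - v1$bands$`p2.5`))
})

test_that("SIR reproduces the Wald answer on an exactly quadratic surface", {
  # full-rank quadratic target; the (theta_emax, beta) block carries the
  # interesting correlation, the remaining dimensions are tight and
  # independent
  ptoy <- model_parameters(1.0, 10, covariate_effects =
    list(baseline_essdai = c(coef = 2.0, center = 10)), sigma = 1)
  A2 <- matrix(c(4, 1, 1, 2), 2)    # precision of (theta_emax, beta)
  V <- solve(A2)
  full_cov <- diag(0.01, 6)         # theta_emax, theta_et50, beta, om1, om2, sigma
  full_cov[c(1, 3), c(1, 3)] <- V
  A_full <- solve(full_cov)
  f <- fake_fit(ptoy, covariance = full_cov)
  mu <- f$coef
  ofv_fn <- function(par) {
    d <- par - mu
    as.numeric(t(d) %*% A_full %*% d)
  }
  s <- sir(f, n_proposal = 4000, n_resample = 1000, inflation = 1.5,
           seed = 5, ofv_fn = ofv_fn)
  sd1 <- sqrt(V[1, 1]); sd2 <- sqrt(V[2, 2])
  sm <- s$summary
  expect_equal(sm$median[sm$parameter == "theta_emax"], 1.0,
               tolerance = 0.15 * sd1)
  expect_equal(sm$median[sm$parameter == "beta_baseline_essdai"], 2.0,
               tolerance = 0.15 * sd2)
  expect_equal(sm$hi95[sm$parameter == "theta_emax"] -
                 sm$lo95[sm$parameter == "theta_emax"],
               2 * 1.96 * sd1, tolerance = 0.15 * 2 * 1.96 * sd1)
  expect_equal(sm$hi95[sm$parameter == "beta_baseline_essdai"] -
                 sm$lo95[sm$parameter == "beta_baseline_essdai"],
               2 * 1.96 * sd2, tolerance = 0.15 * 2 * 1.96 * sd2)
})

test_that("SIR validates its sample sizes and flags degenerate weights", {
  ptoy <- model_parameters(1.0, 10, sigma = 1)
  f <- fake_fit(ptoy, covariance = diag(0.1, 5))
  expect_error(sir(f, n_proposal = 100, n_resample = 200),
               "n_resample")
  # a proposal vastly wider than the target starves the resample
  A <- diag(5) * 1e4
  mu <- f$coef
  ofv_fn <- function(par) as.numeric(t(par - mu) %*% A %*% (par - mu))
  expect_error(sir(f, n_proposal = 300, n_resample = 50, inflation = 500,
                   seed = 2, ofv_fn = ofv_fn),
               "ESS")
})

test_that("SIR medians track the point estimates on a fitted corpus", {
  ds <- toy_dataset(n_trials = 8, seed = 66)
  f <- fit_model(ds, character())
  expect_true(f$converged)
  s <- sir(f, ds, n_proposal = 1500, n_resample = 300, seed = 3)
  est <- c(f$params$theta_emax, f$params$theta_et50, f$params$sigma)
  med <- s$summary$median[match(c("theta_emax", "theta_et50", "sigma"),
                                s$summary$parameter)]
  expect_equal(med, est, tolerance = 0.25)
  expect_true(all(s$summary$lo95 <= s$summary$median &
                  s$summary$median <= s$summary$hi95))
})
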