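# Fixture builders shared across test files. Everything is generated in
# code; no binary or stored data.

table2_params <- function() default_parameters()

# small simulated corpus
toy_dataset <- function(n_trials = 3, seed = 11,
                        params = default_parameters(),
                        visits = c(3L, 4L)) {
  d <- sample_design(n_trials, seed = seed, visits_per_trial = visits)
  simulate_dataset(d, params, seed = seed + 1000)
}

# hand-built design so tests control schedules exactly (bypasses
# sample_design's visit grid)
manual_design <- function(trials, schedules) {
  structure(list(trials = trials, schedules = schedules),
            class = "simulation_design")
}

one_trial_design <- function(times, n = 25L, baseline = 10.1,
                             duration = max(times, 1)) {
  tr <- data.frame(trial_id = "T1", n_subjects = as.integer(n),
                   duration_weeks = duration, baseline_essdai = baseline,
                   age_years = 54.4, male_pct = 5, diagnosis_years = 5.3,
                   base_therapy_pct = 78.5)
  manual_design(tr, list(T1 = times))
}

# dataset lying exactly on the typical curve (no noise, no random effects)
noise_free_dataset <- function(params = default_parameters(),
                               baselines = c(5, 10.1, 13),
                               times = c(8, 16, 24), n = 30L) {
  nt <- length(baselines)
  trs <- data.frame(trial_id = sprintf("T%d", seq_len(nt)),
                    n_subjects = as.integer(n), duration_weeks = max(times),
                    baseline_essdai = baselines, age_years = 54.4,
                    male_pct = 5, diagnosis_years = 5.3,
                    base_therapy_pct = 78.5)
  p0 <- model_parameters(params$theta_emax, params$theta_et50,
                         covariate_effects = params$covariate_effects,
                         omega_emax = 0, omega_et50 = 0, sigma = 0)
  simulate_dataset(manual_design(trs, setNames(rep(list(times), nt),
                                               trs$trial_id)),
                   p0, seed = 1)
}

# minimal placebo_fit object for tests that do not need a real fit
fake_fit <- function(params, ds = NULL, covariance = NULL,
                     rse_pct = NULL) {
  covariates <- names(params$covariate_effects)
  centers <- lapply(params$covariate_effects, function(e) e[["center"]])
  names(centers) <- covariates
  pn <- placeboMBMA:::.par_names(covariates)
  coef <- placeboMBMA:::.params_to_par(params)
  names(coef) <- pn
  if (!is.null(covariance)) dimnames(covariance) <- list(pn, pn)
  structure(list(params = params, ofv = NA_real_, coef = coef,
                 covariance = covariance,
                 se = setNames(rep(NA_real_, length(pn)), pn),
                 rse_pct = if (is.null(rse_pct))
                   setNames(rep(NA_real_, length(pn)), pn) else rse_pct,
                 ebes = NULL, converged = TRUE,
                 n_obs = if (is.null(ds)) NA_integer_ else n_obs(ds),
                 n_trials = if (is.null(ds)) NA_integer_ else n_trials(ds),
                 covariates = covariates, centers = centers,
                 config = fit_config(), data = ds),
            class = "placebo_fit")
}

# two-trial CSV text in the canonical long format
tiny_csv_text <- function() {
  c("trial_id,time_weeks,change_essdai,n_subjects,baseline_essdai,age_years,male_pct,duration_weeks,diagnosis_years,base_therapy_pct",
    "T1,4,-0.8,20,9.5,55,5,24,4.2,80",
    "T1,12,-1.9,20,9.5,55,5,24,4.2,80",
    "T1,24,-2.4,18,9.5,55,5,24,4.2,80",
    "T2,12,-1.1,40,6.2,,10,48,6.0,50",
    "T2,24,-1.8,40,6.2,,10,48,6.0,50",
    "T2,48,-2.2,35,6.2,,10,48,6.0,50")
}

write_tiny_csv <- function(path = tempfile(fileext = ".csv"),
                           lines = tiny_csv_text()) {
  writeLines(lines, path)
  path
}
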