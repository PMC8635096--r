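# Synthetic trial-corpus generator. Emulates the design distributions of
# the published 13-trial placebo corpus (arm sizes 4-95 with median near
# 19, durations 12-48 weeks with median 24, baseline ESSDAI 2.5-13.1,
# median 10.1) and simulates observations under the same generative model
# the analysis assumes: Emax time course, additive eta on Emax,
# exponential eta on ET50, residual SD sigma/sqrt(N).

.visit_grid <- c(4, 8, 12, 16, 24, 28, 36, 48)
.duration_choices <- c(12, 16, 24, 28, 48)

#' Sample a trial-corpus design
#'
#' Draws per-trial arm sizes, treatment durations, visit schedules and
#' covariates from distributions matched to the published corpus
#' summary: arm sizes log-uniform on \[4, 95\] (median
#' \eqn{\sqrt{4\cdot 95} \approx 19.5}), durations uniform over
#' \{12, 16, 24, 28, 48\} weeks (median 24), baseline ESSDAI uniform on
#' \[2.5, 13.1\], age uniform on \[48.8, 60.2\] years, percent male
#' uniform on \[0, 22.2\], time since diagnosis uniform on \[1, 8.9\]
#' years, percent on base therapy uniform on \[0, 100\]. Visit schedules
#' are random subsets of \{4, 8, 12, 16, 24, 28, 36, 48\} truncated at
#' the trial duration, always retaining the final visit.
#'
#' @param n_trials Number of trials to design (>= 1).
#' @param seed Integer seed; the same seed reproduces the design.
#' @param visits_per_trial Range (length-2 integer) of the number of
#'   post-baseline visits per trial before truncation at the duration.
#' @return An object of class `simulation_design`: list with `trials`
#'   (data frame of arm size, duration and covariates) and `schedules`
#'   (per-trial visit weeks).
#' @export
#' @examples
#' d <- sample_design(13, seed = 42)
#' range(d$trials$baseline_essdai)
sample_design <- function(n_trials, seed, visits_per_trial = c(2L, 4L)) {
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1)
    stop("n_trials must be a positive integer")
  n_trials <- as.integer(n_trials)
  stopifnot(length(visits_per_trial) == 2L, visits_per_trial[1] >= 1)
  withr_seed(seed, {
    ids <- sprintf("S%02d", seq_len(n_trials))
    n_arm <- round(exp(runif(n_trials, log(4), log(95))))
    n_arm <- pmin(pmax(n_arm, 4L), 95L)
    duration <- sample(.duration_choices, n_trials, replace = TRUE)
    trials <- data.frame(
      trial_id = ids,
      n_subjects = as.integer(n_arm),
      duration_weeks = duration,
      baseline_essdai = round(runif(n_trials, 2.5, 13.1), 1),
      age_years = round(runif(n_trials, 48.8, 60.2), 1),
      male_pct = round(runif(n_trials, 0, 22.2), 1),
      diagnosis_years = round(runif(n_trials, 1, 8.9), 1),
      base_therapy_pct = round(runif(n_trials, 0, 100), 1))
    schedules <- lapply(seq_len(n_trials), function(i) {
      cand <- .visit_grid[.visit_grid <= duration[i]]
      k <- sample(seq(visits_per_trial[1], visits_per_trial[2]), 1L)
      final <- max(cand)
      earlier <- setdiff(cand, final)
      picked <- if (k > 1 && length(earlier))
        sample(earlier, min(k - 1L, length(earlier)))
      else numeric()
      sort(c(picked, final))
    })
    names(schedules) <- ids
    structure(list(trials = trials, schedules = schedules),
              class = "simulation_design")
  })
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf("simulation_design: %d trials, arm sizes %d-%d, durations %g-%g weeks\n",
              nrow(x$trials), min(x$trials$n_subjects), max(x$trials$n_subjects),
              min(x$trials$duration_weeks), max(x$trials$duration_weeks)))
  invisible(x)
}

#' Simulate a trial-level dataset under the mixed-effects model
#'
#' For each trial draws the additive Emax random effect
#' \eqn{\eta_{1i} \sim N(0, \omega_{Emax}^2)} and the log-ET50 random
#' effect \eqn{\eta_{2i} \sim N(0, \omega_{ET50}^2)} (independent),
#' evaluates the Emax time course at the trial's visit weeks, and adds
#' arm-level residual noise with standard deviation
#' \eqn{\sigma/\sqrt{N_{ij}}}. The residual acts on the observed mean
#' change (aggregate-level noise), mirroring the arm-level endpoint.
#'
#' @param design A [sample_design()] object (or one built by hand with
#'   the same structure).
#' @param params True [model_parameters()] to simulate under.
#' @param seed Integer seed; the same seed reproduces the dataset
#'   bitwise.
#' @return A valid [meta_dataset()].
#' @export
simulate_dataset <- function(design, params, seed) {
  stopifnot(inherits(design, "simulation_design") ||
              (is.list(design) && !is.null(design$trials) && !is.null(design$schedules)),
            inherits(params, "model_parameters"))
  trials <- design$trials
  withr_seed(seed, {
    obs <- lapply(seq_len(nrow(trials)), function(i) {
      tr <- trials[i, , drop = FALSE]
      tt <- design$schedules[[tr$trial_id]]
      e1 <- rnorm(1, 0, params$omega_emax)
      e2 <- rnorm(1, 0, params$omega_et50)
      f <- predict_change(params, tr, list(eta_emax = e1, eta_et50 = e2), tt)
      eps <- rnorm(length(tt), 0, params$sigma / sqrt(tr$n_subjects))
      data.frame(trial_id = tr$trial_id, time_weeks = tt,
                 change_essdai = f + eps, n_subjects = tr$n_subjects)
    })
    obs <- do.call(rbind, obs)
    cov <- trials[c("trial_id", .cov_cols)]
    meta_dataset(obs, cov,
                 provenance = sprintf("simulated (seed %d)", as.integer(seed)))
  })
}
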