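# Virtual-placebo-control evaluation of external single-arm trials: the
# observed mean changes are compared point by point against the
# model-simulated 95% band of the typical placebo response at the
# trial's own baseline.

#' Construct a single-arm trial record
#'
#' @param label Trial label (free text).
#' @param baseline_essdai Baseline ESSDAI score of the arm (points).
#' @param observations Data frame with columns `time_weeks`,
#'   `change_essdai` (mean change from baseline) and `se` (standard
#'   error of the mean change; displayed but not used in the
#'   band-containment rule). Times must be strictly increasing, SE >= 0.
#' @param n_subjects Number of subjects in the arm.
#' @return Object of class `single_arm_trial`.
#' @export
single_arm_trial <- function(label, baseline_essdai, observations, n_subjects) {
  stopifnot(is.character(label), length(label) == 1L,
            is.numeric(baseline_essdai), baseline_essdai > 0,
            is.data.frame(observations),
            is.numeric(n_subjects), n_subjects >= 1)
  need <- c("time_weeks", "change_essdai", "se")
  miss <- setdiff(need, names(observations))
  if (length(miss)) stop("observations lack column(s): ", paste(miss, collapse = ", "))
  obs <- observations[need]
  if (is.unsorted(obs$time_weeks, strictly = TRUE))
    stop("observation times must be strictly increasing")
  if (any(obs$se < 0, na.rm = TRUE)) stop("standard errors must be >= 0")
  structure(list(label = label, baseline_essdai = baseline_essdai,
                 observations = obs, n_subjects = as.integer(n_subjects)),
            class = "single_arm_trial")
}

#' @export
print.single_arm_trial <- function(x, ...) {
  cat(sprintf("single_arm_trial '%s': n = %d, baseline ESSDAI %.1f, %d time points\n",
              x$label, x$n_subjects, x$baseline_essdai, nrow(x$observations)))
  print(x$observations, row.names = FALSE)
  invisible(x)
}

#' Read a single-arm trial from CSV
#'
#' Format: '#'-prefixed header lines `# label: ...`, `# baseline_essdai:
#' ...`, `# n_subjects: ...`, followed by a 3-column CSV
#' (`time_weeks, change_essdai, se`).
#'
#' @param path File path.
#' @return A [single_arm_trial()].
#' @export
read_single_arm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  for (k in c("label", "baseline_essdai", "n_subjects"))
    if (is.null(meta[[k]])) stop("single-arm CSV lacks header metadata '", k, "'")
  obs <- read.csv(textConnection(lines[!grepl("^#", lines)]))
  single_arm_trial(meta$label, as.numeric(meta$baseline_essdai), obs,
                   as.integer(meta$n_subjects))
}

#' Write a single-arm trial to CSV
#'
#' @param trial A [single_arm_trial()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_single_arm <- function(trial, path) {
  stopifnot(inherits(trial, "single_arm_trial"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# label: %s", trial$label),
               sprintf("# baseline_essdai: %.10g", trial$baseline_essdai),
               sprintf("# n_subjects: %d", trial$n_subjects)), con)
  write.csv(trial$observations, con, row.names = FALSE)
  invisible(path)
}

#' Compare a single-arm trial against the virtual placebo control
#'
#' Builds the typical-response 95% band ([typical_ci()]) at the trial's
#' baseline over the trial's observation times and flags each observed
#' mean change as inside or outside. The efficacy verdict is
#' `exceeds-placebo` when at least one observation falls below the lower
#' band limit (more improvement than the placebo response explains), and
#' `comparable-to-placebo` otherwise. Points above the upper limit
#' (less improvement than placebo) are flagged separately as
#' `possible_harm` but do not drive the efficacy verdict.
#'
#' @param fit A converged [fit_model()] result usable by [typical_ci()].
#' @param trial A [single_arm_trial()].
#' @param n_draws Monte-Carlo draws for the band (default 10000).
#' @param seed Integer seed.
#' @return Object of class `single_arm_comparison`: list with `table`
#'   (per time point: observed change, band, `inside`, `below_lo`,
#'   `above_hi`), `verdict`, `band` (the [typical_ci()] object),
#'   `trial`.
#' @export
compare_single_arm <- function(fit, trial, n_draws = 10000L, seed = 1L) {
  stopifnot(inherits(fit, "placebo_fit"), inherits(trial, "single_arm_trial"))
  if (is.na(trial$baseline_essdai)) stop("trial baseline is missing")
  tci <- typical_ci(fit, trial$baseline_essdai, trial$observations$time_weeks,
                    n_draws = n_draws, seed = seed)
  b <- tci$band
  y <- trial$observations$change_essdai
  below <- y < b$lo95
  above <- y > b$hi95
  tab <- data.frame(time_weeks = b$time_weeks,
                    observed = y, se = trial$observations$se,
                    lo95 = b$lo95, median = b$median, hi95 = b$hi95,
                    inside = !(below | above),
                    below_lo = below, above_hi = above)
  verdict <- if (any(below)) "exceeds-placebo" else "comparable-to-placebo"
  structure(list(table = tab, verdict = verdict, band = tci, trial = trial),
            class = "single_arm_comparison")
}

#' @export
print.single_arm_comparison <- function(x, ...) {
  cat(sprintf("Single-arm comparison '%s' (baseline ESSDAI %.1f, n = %d)\n",
              x$trial$label, x$trial$baseline_essdai, x$trial$n_subjects))
  cat(sprintf("  verdict: %s%s\n", x$verdict,
              if (any(x$table$above_hi)) " (possible-harm points present)" else ""))
  print(transform(x$table, observed = round(observed, 2),
                  lo95 = round(lo95, 2), median = round(median, 2),
                  hi95 = round(hi95, 2)), row.names = FALSE)
  invisible(x)
}
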