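# Trial-level dataset container and CSV I/O.
#
# The canonical on-disk format is a long CSV, one row per placebo arm per
# follow-up time, with trial covariates repeated on every row of the trial:
#   trial_id, time_weeks, change_essdai, n_subjects,
#   baseline_essdai, age_years, male_pct, duration_weeks,
#   diagnosis_years, base_therapy_pct
# Empty cell = missing; UTF-8; "." decimal.

.obs_cols <- c("trial_id", "time_weeks", "change_essdai", "n_subjects")
.cov_cols <- c("baseline_essdai", "age_years", "male_pct", "duration_weeks",
               "diagnosis_years", "base_therapy_pct")
.optional_covs <- c("age_years", "male_pct", "diagnosis_years",
                    "base_therapy_pct")

#' Construct a trial-level meta-analysis dataset
#'
#' A `meta_dataset` holds the longitudinal observations (one row per arm
#' per follow-up time) and the trial-level covariates of a placebo-arm
#' corpus. Invariants enforced: unique trial ids, every trial has at
#' least one observation, strictly increasing observation times within a
#' trial, positive per-timepoint sample sizes, positive baseline ESSDAI,
#' percentages within \[0, 100\] where present. A missing per-timepoint
#' sample size is carried forward from the previous time point of the
#' same trial (the arm size is assumed constant unless stated otherwise).
#'
#' @param observations Data frame with columns `trial_id`, `time_weeks`,
#'   `change_essdai`, `n_subjects`.
#' @param covariates Data frame with columns `trial_id`,
#'   `baseline_essdai`, `age_years`, `male_pct`, `duration_weeks`,
#'   `diagnosis_years`, `base_therapy_pct` (optional covariates may be
#'   `NA`).
#' @param provenance Free-text notes carried along with the dataset.
#' @return An object of class `meta_dataset`.
#' @export
meta_dataset <- function(observations, covariates, provenance = character()) {
  stopifnot(is.data.frame(observations), is.data.frame(covariates))
  miss <- setdiff(.obs_cols, names(observations))
  if (length(miss)) stop("observations lack column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(c("trial_id", .cov_cols), names(covariates))
  if (length(miss)) stop("covariates lack column(s): ", paste(miss, collapse = ", "))

  obs <- observations[.obs_cols]
  obs$trial_id <- as.character(obs$trial_id)
  cov <- covariates[c("trial_id", .cov_cols)]
  cov$trial_id <- as.character(cov$trial_id)

  if (anyDuplicated(cov$trial_id))
    stop("duplicate trial_id in covariates: ",
         paste(unique(cov$trial_id[duplicated(cov$trial_id)]), collapse = ", "))
  if (!all(obs$trial_id %in% cov$trial_id))
    stop("observations reference trial_id(s) without covariates: ",
         paste(setdiff(obs$trial_id, cov$trial_id), collapse = ", "))
  if (!all(cov$trial_id %in% obs$trial_id))
    stop("trial(s) without any observation: ",
         paste(setdiff(cov$trial_id, obs$trial_id), collapse = ", "))

  # sort by trial then time; LOCF for missing per-timepoint N
  obs <- obs[order(match(obs$trial_id, cov$trial_id), obs$time_weeks), ,
             drop = FALSE]
  rownames(obs) <- NULL
  for (id in cov$trial_id) {
    i <- which(obs$trial_id == id)
    tt <- obs$time_weeks[i]
    if (any(!is.finite(tt)) || any(tt < 0))
      stop("trial '", id, "': time_weeks must be finite and >= 0")
    if (anyDuplicated(tt))
      stop("trial '", id, "': duplicate observation time(s) ",
           paste(unique(tt[duplicated(tt)]), collapse = ", "))
    n <- obs$n_subjects[i]
    if (is.na(n[1])) stop("trial '", id, "': n_subjects missing at the first time point")
    for (k in seq_along(n)[-1]) if (is.na(n[k])) n[k] <- n[k - 1]
    obs$n_subjects[i] <- n
  }
  if (any(!is.finite(obs$change_essdai)))
    stop("change_essdai must be finite for every observation")
  if (any(obs$n_subjects < 1) || any(obs$n_subjects != round(obs$n_subjects)))
    stop("n_subjects must be positive integers")
  obs$n_subjects <- as.integer(obs$n_subjects)

  if (any(is.na(cov$baseline_essdai)) || any(cov$baseline_essdai <= 0))
    stop("baseline_essdai is mandatory and must be > 0 for every trial")
  if (any(is.na(cov$duration_weeks)) || any(cov$duration_weeks <= 0))
    stop("duration_weeks is mandatory and must be > 0 for every trial")
  for (nm in c("male_pct", "base_therapy_pct")) {
    v <- cov[[nm]]
    if (any(!is.na(v) & (v < 0 | v > 100)))
      stop(nm, " must lie in [0, 100] where present")
  }
  rownames(cov) <- NULL

  structure(list(observations = obs, covariates = cov,
                 provenance = as.character(provenance)),
            class = "meta_dataset")
}

#' @export
print.meta_dataset <- function(x, ...) {
  cat(sprintf("meta_dataset: %d trials, %d observations, %d subjects\n",
              nrow(x$covariates), nrow(x$observations),
              sum(vapply(split(x$observations$n_subjects, x$observations$trial_id),
                         max, numeric(1)))))
  cat(sprintf("  baseline ESSDAI %.1f-%.1f, follow-up to %.0f weeks\n",
              min(x$covariates$baseline_essdai), max(x$covariates$baseline_essdai),
              max(x$observations$time_weeks)))
  if (length(x$provenance)) cat("  provenance:", x$provenance[1], "\n")
  invisible(x)
}

#' Number of trials / observations in a meta_dataset
#' @param ds A [meta_dataset()].
#' @return Integer count.
#' @export
n_trials <- function(ds) nrow(ds$covariates)

#' @rdname n_trials
#' @export
n_obs <- function(ds) nrow(ds$observations)

#' Read a trial-level dataset from a long CSV
#'
#' Expects the canonical columns `trial_id, time_weeks, change_essdai,
#' n_subjects, baseline_essdai, age_years, male_pct, duration_weeks,
#' diagnosis_years, base_therapy_pct` (empty cell = missing). Covariates
#' must be constant within a trial. Numeric columns are validated cell
#' by cell so parse errors name the offending row.
#'
#' @param path Path to the CSV file.
#' @return A validated [meta_dataset()].
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = TRUE,
                  comment.char = "#", na.strings = "")
  need <- c(.obs_cols, .cov_cols)
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("dataset CSV is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  num_cols <- setdiff(need, "trial_id")
  for (nm in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    bad <- which(!is.na(raw[[nm]]) & is.na(v))
    if (length(bad))
      stop("non-numeric value in column '", nm, "' at data row ", bad[1],
           ": '", raw[[nm]][bad[1]], "'")
    raw[[nm]] <- v
  }
  dup <- duplicated(raw[c("trial_id", "time_weeks")])
  if (any(dup))
    stop("duplicate (trial_id, time_weeks) row(s): ",
         paste(unique(paste0("(", raw$trial_id[dup], ", ",
                             raw$time_weeks[dup], ")")), collapse = ", "))
  cov <- unique(raw[c("trial_id", .cov_cols)])
  if (anyDuplicated(cov$trial_id))
    stop("covariates are not constant within trial(s): ",
         paste(unique(cov$trial_id[duplicated(cov$trial_id)]), collapse = ", "))
  meta_dataset(raw[.obs_cols], cov,
               provenance = paste("read from", basename(path)))
}

#' Write a trial-level dataset to the canonical long CSV
#'
#' Produces a CSV that [read_dataset()] inverts exactly (round-trip
#' identity up to provenance notes). Missing covariates become empty
#' cells.
#'
#' @param ds A [meta_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "meta_dataset"))
  out <- merge(ds$observations, ds$covariates, by = "trial_id", sort = FALSE)
  out <- out[order(match(out$trial_id, ds$covariates$trial_id), out$time_weeks),
             c(.obs_cols, .cov_cols)]
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write dataset to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Apply the covariate missingness rules
#'
#' Covariates missing in at least `max_missing_fraction` of trials are
#' flagged unusable for covariate modelling (they keep their values but
#' are removed from the candidate set); remaining missing values are
#' imputed with the across-trial median of that covariate. The
#' missingness fraction is computed per trial, the analysis unit.
#' Idempotent, and never touches the observation records.
#'
#' @param ds A [meta_dataset()].
#' @param max_missing_fraction Missingness threshold; a covariate with
#'   `mean(is.na) >= max_missing_fraction` is excluded (default 0.4).
#' @return A list with elements `dataset` (the prepared
#'   [meta_dataset()], carrying attribute `"unusable_covariates"`) and
#'   `report` (data frame of every action taken).
#' @export
#' @examples
#' ds <- simulate_dataset(sample_design(6, seed = 1), default_parameters(),
#'                        seed = 2)
#' prepare_covariates(ds)$report
prepare_covariates <- function(ds, max_missing_fraction = 0.4) {
  stopifnot(inherits(ds, "meta_dataset"),
            max_missing_fraction > 0, max_missing_fraction <= 1)
  cov <- ds$covariates
  unusable <- attr(ds, "unusable_covariates")
  if (is.null(unusable)) unusable <- character()
  rows <- list()
  for (nm in .optional_covs) {
    v <- cov[[nm]]
    frac <- mean(is.na(v))
    if (nm %in% unusable || frac >= max_missing_fraction) {
      unusable <- union(unusable, nm)
      rows[[nm]] <- data.frame(covariate = nm, action = "dropped",
                               n_missing = sum(is.na(v)),
                               missing_fraction = frac,
                               imputed_value = NA_real_)
    } else if (any(is.na(v))) {
      med <- median(v, na.rm = TRUE)
      cov[[nm]][is.na(v)] <- med
      rows[[nm]] <- data.frame(covariate = nm, action = "imputed",
                               n_missing = sum(is.na(v)),
                               missing_fraction = frac,
                               imputed_value = med)
    }
  }
  report <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
            else data.frame(covariate = character(), action = character(),
                            n_missing = integer(), missing_fraction = numeric(),
                            imputed_value = numeric())
  out <- meta_dataset(ds$observations, cov, provenance = ds$provenance)
  attr(out, "unusable_covariates") <- unusable
  list(dataset = out, report = report)
}

#' Covariates usable for model building after preparation
#'
#' @param ds A prepared [meta_dataset()] (output of
#'   [prepare_covariates()]); an unprepared dataset returns all
#'   complete covariates.
#' @return Character vector of covariate names with no missing values
#'   and not flagged unusable.
#' @export
usable_covariates <- function(ds) {
  stopifnot(inherits(ds, "meta_dataset"))
  unusable <- attr(ds, "unusable_covariates")
  cand <- setdiff(.cov_cols, unusable)
  cand[vapply(cand, function(nm) !any(is.na(ds$covariates[[nm]])), logical(1))]
}
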