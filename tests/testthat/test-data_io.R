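test_that("a long CSV maps to a validated dataset, grouped and sorted", {
  ds <- read_dataset(write_tiny_csv())
  expect_s3_class(ds, "meta_dataset")
  expect_equal(n_trials(ds), 2L)
  expect_equal(n_obs(ds), 6L)
  expect_equal(ds$observations$time_weeks[ds$observations$trial_id == "T1"],
               c(4, 12, 24))
  # missing optional covariate arrives as NA
  expect_true(is.na(ds$covariates$age_years[ds$covariates$trial_id == "T2"]))
})

test_that("malformed CSVs are rejected with informative errors", {
  lines <- tiny_csv_text()
  expect_error(read_dataset(write_tiny_csv(lines = lines[-1])),
               "missing mandatory column")
  dup <- c(lines, "T1,12,-2.0,20,9.5,55,5,24,4.2,80")
  expect_error(read_dataset(write_tiny_csv(lines = dup)),
               "duplicate \\(trial_id, time_weeks\\)")
  bad <- lines; bad[3] <- "T1,12,abc,20,9.5,55,5,24,4.2,80"
  expect_error(read_dataset(write_tiny_csv(lines = bad)),
               "non-numeric value in column 'change_essdai' at data row 2")
  expect_error(read_dataset(tempfile()), "file not found")
})

test_that("write_dataset/read_dataset round-trip is the identity", {
  for (seed in c(3, 17, 91)) {
    ds <- toy_dataset(n_trials = 4, seed = seed)
    # inject a missing optional covariate to exercise empty cells
    ds$covariates$diagnosis_years[2] <- NA
    ds <- meta_dataset(ds$observations, ds$covariates)
    path <- tempfile(fileext = ".csv")
    write_dataset(ds, path)
    back <- read_dataset(path)
    expect_equal(back$observations, ds$observations)
    expect_equal(back$covariates, ds$covariates)
  }
})

test_that("dataset invariants are enforced", {
  ds <- read_dataset(write_tiny_csv())
  # a trial without observations is rejected
  expect_error(meta_dataset(
    ds$observations[ds$observations$trial_id == "T1", ], ds$covariates),
    "without any observation")
  # baseline ESSDAI is mandatory
  cov2 <- ds$covariates; cov2$baseline_essdai[1] <- NA
  expect_error(meta_dataset(ds$observations, cov2), "baseline_essdai")
  # missing per-timepoint N is carried forward from the previous visit
  obs <- ds$observations
  obs$n_subjects[obs$trial_id == "T2" & obs$time_weeks == 24] <- NA
  ds2 <- meta_dataset(obs, ds$covariates)
  expect_equal(ds2$observations$n_subjects[
    ds2$observations$trial_id == "T2"], c(40L, 40L, 35L))
})

test_that("covariates missing in >= 40% of trials are dropped, the rest imputed", {
  n <- 10
  obs <- data.frame(trial_id = sprintf("T%02d", 1:n), time_weeks = 12,
                    change_essdai = -1, n_subjects = 20L)
  cov <- data.frame(trial_id = sprintf("T%02d", 1:n), baseline_essdai = 9,
                    age_years = c(rep(NA, 4), rep(55, 6)),
                    male_pct = 5, duration_weeks = 24,
                    diagnosis_years = c(1, 3, NA, 7, 9, NA, NA, NA, NA, NA),
                    base_therapy_pct = 70)
  # age: 4/10 = 40% missing -> dropped (inclusive threshold);
  # diagnosis_years: 60% missing -> dropped
  prep <- prepare_covariates(meta_dataset(obs, cov))
  expect_setequal(prep$report$covariate[prep$report$action == "dropped"],
                  c("age_years", "diagnosis_years"))
  expect_false("age_years" %in% usable_covariates(prep$dataset))

  # below the threshold the median fills in: {1,3,7,9} -> 5
  cov$age_years <- 55
  cov$diagnosis_years <- c(1, 3, NA, 7, 9, 2, 4, 6, 8, 5)
  prep2 <- prepare_covariates(meta_dataset(obs, cov))
  expect_equal(prep2$report$action, "imputed")
  expect_equal(prep2$dataset$covariates$diagnosis_years[3], 5)
  expect_true("diagnosis_years" %in% usable_covariates(prep2$dataset))
})

test_that("prepare_covariates is idempotent and never touches observations", {
  ds <- toy_dataset(n_trials = 5, seed = 23)
  ds$covariates$age_years[c(1, 3)] <- NA
  ds <- meta_dataset(ds$observations, ds$covariates)
  p1 <- prepare_covariates(ds)
  p2 <- prepare_covariates(p1$dataset)
  expect_equal(p2$dataset$covariates, p1$dataset$covariates)
  expect_equal(attr(p2$dataset, "unusable_covariates"),
               attr(p1$dataset, "unusable_covariates"))
  expect_equal(p1$dataset$observations, ds$observations)
  # a complete dataset passes through unchanged with an empty report
  ds0 <- toy_dataset(n_trials = 4, seed = 5)
  p0 <- prepare_covariates(ds0)
  expect_equal(nrow(p0$report), 0L)
  expect_equal(p0$dataset$covariates, ds0$covariates)
})
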