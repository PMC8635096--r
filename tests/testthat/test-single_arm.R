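p2 <- table2_params()

make_trial <- function(times, changes, se = 0.4, baseline = 8.8,
                       label = "fixture", n = 30L) {
  single_arm_trial(label, baseline,
                   data.frame(time_weeks = times, change_essdai = changes,
                              se = se), n)
}

test_that("trial records validate their invariants", {
  expect_error(make_trial(c(12, 12), c(-1, -2)), "strictly increasing")
  expect_error(make_trial(12, -1, se = -0.1), "standard errors")
  tr <- make_trial(c(12, 28), c(-1.5, -2.1))
  expect_s3_class(tr, "single_arm_trial")
})

test_that("single-arm CSV round-trips through the header format", {
  tr <- make_trial(c(12, 16, 28), c(-1.2, -1.6, -2.0), baseline = 5.5,
                   label = "cyclosporine-like synthetic")
  path <- tempfile(fileext = ".csv")
  write_single_arm(tr, path)
  back <- read_single_arm(path)
  expect_equal(back$label, tr$label)
  expect_equal(back$baseline_essdai, 5.5)
  expect_equal(back$n_subjects, 30L)
  expect_equal(back$observations, tr$observations)
  expect_error(read_single_arm(tempfile()), "file not found")
})

test_that("observations on the typical curve are judged comparable to placebo", {
  ds <- toy_dataset(n_trials = 3, seed = 10)
  f <- fake_fit(p2, ds, covariance = diag(c(0.4, 0.05, 0.01, rep(1e-8, 3))))
  times <- c(12, 16, 28)
  tr <- make_trial(times, typical_response(p2, 8.8, times))
  cmp <- compare_single_arm(f, tr, n_draws = 4000, seed = 3)
  expect_true(all(cmp$table$inside))
  expect_equal(cmp$verdict, "comparable-to-placebo")
})

test_that("a far outlier on the improvement side exceeds the placebo band", {
  ds <- toy_dataset(n_trials = 3, seed = 10)
  f <- fake_fit(p2, ds, covariance = diag(c(0.4, 0.05, 0.01, rep(1e-8, 3))))
  tr <- make_trial(24, -20, baseline = 8)
  cmp <- compare_single_arm(f, tr, n_draws = 2000, seed = 3)
  expect_true(cmp$table$below_lo)
  expect_equal(cmp$verdict, "exceeds-placebo")
  # worse-than-placebo points flag possible harm but not efficacy
  tr_harm <- make_trial(24, +5, baseline = 8)
  cmp_h <- compare_single_arm(f, tr_harm, n_draws = 2000, seed = 3)
  expect_true(cmp_h$table$above_hi)
  expect_equal(cmp_h$verdict, "comparable-to-placebo")
})

test_that("the verdict is monotone in the observed improvement", {
  ds <- toy_dataset(n_trials = 3, seed = 10)
  f <- fake_fit(p2, ds, covariance = diag(c(0.4, 0.05, 0.01, rep(1e-8, 3))))
  times <- c(12, 28)
  base_changes <- typical_response(p2, 8.8, times)
  verdicts <- vapply(seq(0, 8, by = 0.5), function(shift) {
    cmp <- compare_single_arm(f, make_trial(times, base_changes - shift),
                              n_draws = 2000, seed = 3)
    cmp$verdict
  }, character(1))
  # once the trial exceeds placebo it stays exceeding as improvement grows
  first <- match("exceeds-placebo", verdicts)
  expect_false(is.na(first))
  expect_true(all(verdicts[first:length(verdicts)] == "exceeds-placebo"))
})

test_that("a zero-width band accepts only exact agreement with the typical curve", {
  ds <- toy_dataset(n_trials = 3, seed = 10)
  f0 <- fake_fit(p2, ds, covariance = diag(0, 6))
  times <- c(12, 24)
  on_curve <- make_trial(times, typical_response(p2, 8.8, times))
  cmp1 <- compare_single_arm(f0, on_curve, n_draws = 500, seed = 1)
  expect_true(all(cmp1$table$inside))
  off <- make_trial(times, typical_response(p2, 8.8, times) - 1e-6)
  cmp2 <- compare_single_arm(f0, off, n_draws = 500, seed = 1)
  expect_false(any(cmp2$table$inside))
})
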