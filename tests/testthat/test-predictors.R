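test_that("baseline prediction is the identity on positive distances", {
  expect_equal(predict_baseline(300), 300)
  expect_equal(predict_baseline(425), 425)
  expect_error(predict_baseline(0), "positive")
})

test_that("average-improvement adds the mean change of the other patients", {
  weekly <- data.frame(
    patient_id = c("i", "j1", "j2"),
    week = c(3, 3, 3),
    mean_distance_m = c(100, 200, 300)
  )
  ends <- c(i = NA, j1 = 220, j2 = 330)
  expect_equal(predict_avg_improvement("i", 3, weekly, ends), 125)

  # no cohort improvement -> own level returned
  ends_flat <- c(i = NA, j1 = 200, j2 = 300)
  expect_equal(predict_avg_improvement("i", 3, weekly, ends_flat), 100)

  # single other patient -> that patient's change
  expect_equal(predict_avg_improvement("i", 3, weekly,
                                       c(i = NA, j1 = 260)), 160)
  expect_error(predict_avg_improvement("i", 3, weekly, c(i = 500)),
               "no other patient")
})

test_that("log fit recovers exact and constant trajectories", {
  f <- fit_log(1:6, 10 * log(1:6) + 300)
  expect_equal(f$a, 10, tolerance = 1e-12)
  expect_equal(f$b, 300, tolerance = 1e-12)
  expect_equal(f$n_points, 6L)

  f0 <- fit_log(c(1, 3, 7), rep(400, 3))
  expect_equal(f0$a, 0, tolerance = 1e-12)
  expect_equal(f0$b, 400, tolerance = 1e-12)

  expect_error(fit_log(c(2, 2, 2), c(1, 2, 3)), "distinct")
  expect_error(fit_log(c(0, 1), c(1, 2)), "> 0")
})

test_that("log fit equals the normal-equations oracle on random instances", {
  set.seed(505)
  for (rep in 1:100) {
    n <- sample(3:15, 1)
    weeks <- sort(runif(n, 0.2, 12))
    d <- runif(1, -50, 50) * log(weeks) + runif(1, 100, 500) + rnorm(n, 0, 30)
    f <- fit_log(weeks, d)
    o <- oracle_logfit(weeks, d)
    expect_equal(f$a, o$a, tolerance = 1e-9)
    expect_equal(f$b, o$b, tolerance = 1e-9)
  }
})

test_that("log fit is equivariant under distance shifts and week scaling", {
  set.seed(506)
  weeks <- c(1, 2, 4, 8, 11)
  d <- 25 * log(weeks) + 310 + rnorm(5, 0, 10)
  f <- fit_log(weeks, d)
  shifted <- fit_log(weeks, d + 42)
  expect_equal(shifted$a, f$a, tolerance = 1e-10)
  expect_equal(shifted$b, f$b + 42, tolerance = 1e-10)
  scaled <- fit_log(3 * weeks, d)
  expect_equal(scaled$a, f$a, tolerance = 1e-10)
  expect_equal(scaled$b, f$b - f$a * log(3), tolerance = 1e-10)
})

test_that("individual log prediction extrapolates exactly and abstains when underdetermined", {
  tests <- data.frame(
    patient_id = "A",
    study_week = c(0, 1, 2, 3, 4),
    distance_m = c(300, 10 * log(1:4) + 300),
    source = c("clinic", rep("app", 4))
  )
  expect_equal(predict_log_individual("A", 4, tests),
               10 * log(12) + 300, tolerance = 1e-12)
  expect_equal(round(predict_log_individual("A", 4, tests), 2), 324.85)
  # flat tests
  tests$distance_m <- 400
  expect_equal(predict_log_individual("A", 4, tests), 400, tolerance = 1e-12)
  # only one app test by week 1 -> abstain
  expect_true(is.na(predict_log_individual("A", 1, tests)))
  # the week-0 clinic test never enters the fit
  expect_true(is.na(predict_log_individual("A", 1.4,
                                           tests[1:2, , drop = FALSE])))
})

test_that("pooled log prediction with a single patient reduces to the individual one", {
  set.seed(507)
  tests <- data.frame(
    patient_id = "A",
    study_week = c(1, 2, 3, 5, 6),
    distance_m = 30 * log(c(1, 2, 3, 5, 6)) + 280 + rnorm(5, 0, 20),
    source = "app"
  )
  expect_equal(predict_log_pooled("A", 6, tests),
               predict_log_individual("A", 6, tests), tolerance = 1e-10)
})

test_that("pooled log prediction is exact for a shared slope with symmetric sampling", {
  ds <- exact_log_cohort(a = 20, b = c(250, 300, 350, 420), test_weeks = 1:8)
  for (p in ds$truth$patient_id) {
    expect_equal(
      predict_log_pooled(p, 8, ds$walktests),
      ds$truth$end_distance_m[ds$truth$patient_id == p],
      tolerance = 1e-10
    )
  }
})

test_that("pooled log prediction on per-patient-constant data returns the patient mean", {
  tests <- data.frame(
    patient_id = rep(c("A", "B"), each = 3),
    study_week = rep(c(1, 3, 5), 2),
    distance_m = rep(c(380, 440), each = 3),
    source = "app"
  )
  expect_equal(predict_log_pooled("A", 5, tests), 380, tolerance = 1e-10)
  expect_equal(predict_log_pooled("B", 5, tests), 440, tolerance = 1e-10)
})

test_that("feature matrix exposes in-clinic candidates and gates telehealth ones", {
  ds <- generate_cohort(cohort_config(n_patients = 6, seed = 51))
  f0 <- build_features(ds, 0)
  expect_false(any(c("mean_dist_upto", "mean_dist_in_week", "log_pred")
                   %in% names(f0)))
  expect_true(all(c("sex", "baseline_6mwt_m", "subj_gap_m", "tug_ratio")
                  %in% names(f0)))
  expect_equal(f0$subj_gap_m,
               ds$baseline$subjective_painfree_m - ds$baseline$baseline_6mwt_m)
  expect_true(all(f0$sex %in% c(0, 1)))

  f3 <- build_features(ds, 3)
  expect_true(all(c("mean_dist_upto", "mean_dist_in_week", "log_pred")
                  %in% names(f3)))

  # identical TUG tests give ratio exactly 1
  ds$baseline$tug2_total_time <- ds$baseline$tug1_total_time
  expect_equal(build_features(ds, 0)$tug_ratio, rep(1, 6))

  # subjective 80 m against a measured 350 m baseline
  ds$baseline$subjective_painfree_m <- 80
  ds$baseline$baseline_6mwt_m <- 350
  expect_equal(build_features(ds, 0)$subj_gap_m, rep(-270, 6))
})

test_that("OLS matches an independent solve and flags rank deficiency by column", {
  set.seed(508)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("f1", "f2", "f3")))
  y <- 2 + X %*% c(1, -2, 0.5) + rnorm(20, 0, 0.3)
  fit <- fit_linreg(X, y)
  o <- oracle_ols(X, y)
  expect_equal(fit$intercept, o[1], tolerance = 1e-9)
  expect_equal(unname(fit$coefficients), o[-1], tolerance = 1e-9)

  # noiseless response is reproduced exactly
  y0 <- as.numeric(5 + X %*% c(2, 0, -1))
  fit0 <- fit_linreg(X, y0)
  expect_equal(predict(fit0, X), y0, tolerance = 1e-9)

  Xc <- cbind(X, dup = X[, "f1"])
  expect_error(fit_linreg(Xc, y), "dup")
  Xconst <- matrix(1, 20, 1, dimnames = list(NULL, "const"))
  expect_error(fit_linreg(Xconst, y), "const")
})
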