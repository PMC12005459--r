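test_that("rmse matches hand values and a two-pass oracle", {
  expect_equal(rmse(c(400, 410), c(410, 400)), 10)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(430, 400), 30)
  expect_error(rmse(1:3, 1:2), "length mismatch")
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  set.seed(601)
  for (rep in 1:10) {
    p <- rnorm(50, 400, 60)
    a <- rnorm(50, 400, 60)
    expect_equal(rmse(p, a), oracle_rmse(p, a), tolerance = 1e-9)
  }
})

test_that("the training-free baseline model gives the same RMSE with or without LOO", {
  ds <- generate_cohort(cohort_config(n_patients = 10, seed = 61))
  res <- loo_evaluate(ds, "baseline", 0)
  direct <- rmse(ds$baseline$baseline_6mwt_m, ds$baseline$end_6mwt_m)
  expect_equal(res$rmse, direct, tolerance = 1e-12)
  expect_equal(res$n, 10L)
})

test_that("average improvement is exact under homogeneous improvement", {
  ids <- c("A", "B", "C", "D")
  v <- c(310, 350, 290, 400)
  tests <- data.frame(
    patient_id = ids, study_week = 3, distance_m = v, source = "app"
  )
  bl <- toy_baseline(ids, end = v + 50, baseline = v)
  ds <- toy_dataset(bl, tests)
  ds$config <- list(n_weeks = 12)
  res <- loo_evaluate(ds, "avg", 3)
  expect_equal(res$rmse, 0, tolerance = 1e-12)
  expect_equal(res$n, 4L)
})

test_that("no patient's LOO prediction depends on their own end distance", {
  ds <- generate_cohort(cohort_config(n_patients = 12, seed = 62))
  for (model in c("baseline", "avg", "log_ind", "log_pool", "linreg")) {
    for (wk in c(0, 3)) {
      if (model %in% c("log_ind", "log_pool") && wk == 0) next
      ref <- loo_evaluate(ds, model, wk)
      for (pid in ds$baseline$patient_id) {
        mut <- ds
        idx <- mut$baseline$patient_id == pid
        mut$baseline$end_6mwt_m[idx] <- mut$baseline$end_6mwt_m[idx] + 150
        res <- loo_evaluate(mut, model, wk)
        own_ref <- ref$predictions$predicted_end_m[
          ref$predictions$patient_id == pid]
        own_mut <- res$predictions$predicted_end_m[
          res$predictions$patient_id == pid]
        expect_equal(own_mut, own_ref, tolerance = 1e-10)
      }
    }
  }
})

test_that("week sweep has the published table structure", {
  ds <- generate_cohort(cohort_config(n_patients = 12, seed = 63))
  sw <- sweep_weeks(ds, models = c("baseline", "avg", "log_ind", "log_pool"),
                    weeks = c(0, 1, 5))
  expect_false(any(sw$model == "baseline" & sw$week > 0))
  expect_false(any(sw$model %in% c("log_ind", "log_pool") & sw$week == 0))
  expect_true(all(sw$rmse >= 0))
  tab <- format_rmse_table(sw)
  expect_equal(tab$week_1[tab$model == "baseline"], "-")
  expect_equal(tab$baseline[tab$model == "log_pool"], "-")
  expect_false(any(tab$week_5[tab$model != "baseline"] == "-"))
})

test_that("pooled log model has near-zero LOO RMSE on a noiseless shared-slope cohort", {
  # shared slope, common test schedule: the per-patient centring offsets
  # cancel and both log models recover the true end distance exactly
  ds <- exact_log_cohort(a = 35, b = seq(240, 420, by = 20), test_weeks = 1:8)
  for (wk in c(2, 4, 8)) {
    res <- loo_evaluate(ds, "log_pool", wk)
    expect_equal(res$n, 10L)
    expect_lt(res$rmse, 1e-6)
    res_i <- loo_evaluate(ds, "log_ind", wk)
    expect_lt(res_i$rmse, 1e-6)
  }
})

test_that("baseline model RMSE on a no-improvement cohort reflects measurement noise", {
  cfg <- cohort_config(n_patients = 400, seed = 65,
                       traj_a_mean = 0, traj_a_sd = 0, meas_noise_sd = 30)
  ds <- generate_cohort(cfg)
  res <- loo_evaluate(ds, "baseline", 0)
  # end - baseline = difference of two independent noise draws: SD 30*sqrt(2)
  expect_equal(res$rmse, 30 * sqrt(2), tolerance = 0.12)
})

test_that("subset search enumerates binomial counts and recovers a planted signal", {
  set.seed(606)
  n <- 25
  ids <- sprintf("P%02d", 1:n)
  bl <- toy_baseline(ids, end = rep(0, n), baseline = rep(300, n))
  bl$age <- sample(50:79, n, replace = TRUE)
  bl$weight_kg <- rnorm(n, 78, 10)
  bl$height_m <- rnorm(n, 1.72, 0.06)
  bl$subjective_painfree_m <- rnorm(n, 80, 30)
  bl$end_6mwt_m <- 200 + 2 * bl$age            # depends on age only
  ds <- toy_dataset(bl, data.frame(
    patient_id = ids, study_week = 0, distance_m = 300, source = "clinic"
  ))
  ds$config <- list(n_weeks = 12)
  cand <- c("age", "weight_kg", "height_m", "subjective_painfree_m", "sex")
  fs <- feature_search(ds, 0, max_features = 2, candidates = cand)
  expect_equal(fs$n_subsets, choose(5, 1) + choose(5, 2))
  expect_equal(fs$per_k$features[1], "age")
  expect_equal(fs$per_k$rmse[1], 0, tolerance = 1e-8)
  expect_equal(fs$best$k, 1L)

  expect_error(
    feature_search(ds, 0, max_features = 4, candidates = cand, budget = 10),
    "budget"
  )
})

test_that("honest subset selection inside folds is reported alongside the pooled grid", {
  set.seed(607)
  ds <- generate_cohort(cohort_config(n_patients = 14, seed = 66))
  fs <- feature_search(ds, 2, max_features = 2, mode = "honest")
  expect_true(is.finite(fs$honest_rmse))
  expect_equal(length(fs$fold_features), fs$n_rows)
  # the pooled-grid optimum cannot be worse than chance would suggest; both
  # summaries come from the same scored grid
  expect_equal(fs$best$rmse, min(fs$per_k$rmse))
})

test_that("overfitting shows up for pure-noise features on fresh replicates", {
  set.seed(608)
  worse <- 0
  for (rep in 1:5) {
    n <- 16
    ids <- sprintf("P%02d", 1:n)
    bl <- toy_baseline(ids, end = rnorm(n, 420, 50), baseline = rep(300, n))
    bl$age <- rnorm(n, 63, 7)
    bl$weight_kg <- rnorm(n, 78, 10)
    bl$height_m <- rnorm(n, 1.72, 0.06)
    bl$subjective_painfree_m <- rnorm(n, 80, 30)
    ds <- toy_dataset(bl, data.frame(
      patient_id = ids, study_week = 0, distance_m = 300, source = "clinic"
    ))
    ds$config <- list(n_weeks = 12)
    fs <- feature_search(ds, 0, max_features = 4,
                         candidates = c("age", "weight_kg", "height_m",
                                        "subjective_painfree_m"))
    if (fs$per_k$rmse[4] >= fs$per_k$rmse[1]) worse <- worse + 1
  }
  expect_gte(worse, 3)
})
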