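#' Baseline (no-improvement) prediction of the study-end distance
#'
#' Reference model: the study-end 6MWT distance is estimated as equal to
#' the baseline distance.
#'
#' @param d0 Baseline 6MWT distance in metres (> 0).
#' @return `d0`.
#' @export
predict_baseline <- function(d0) {
  if (any(!is.finite(d0) | d0 <= 0)) {
    stop("baseline distance must be positive", call. = FALSE)
  }
  d0
}

#' Average-improvement prediction
#'
#' Assumes all patients improve similarly: the mean change from week `n` to
#' the study end, computed over the *other* patients with both values, is
#' added to the target patient's week-`n` distance
#' (`d_hat = d_n_i + mean_j(d_end_j - d_n_j)`).
#'
#' @param patient Patient id to predict for.
#' @param week Week `n` of prediction.
#' @param weekly Weekly series from [aggregate_weekly()]; week-`n` levels
#'   are taken with carry-forward ([weekly_distance_cf()]).
#' @param end_distances Named vector of measured study-end distances.
#' @param exclude Further patient ids to drop from the averaging set (used
#'   by the leave-one-out harness; `patient` is always excluded).
#' @return Predicted end distance (m), or `NA` if the patient has no
#'   distance by week `n`.
#' @export
predict_avg_improvement <- function(patient, week, weekly, end_distances,
                                    exclude = NULL) {
  d_n <- weekly_distance_cf(weekly, week)
  if (!patient %in% names(d_n) || is.na(d_n[patient])) return(NA_real_)
  others <- setdiff(names(end_distances), c(patient, exclude))
  others <- others[!is.na(end_distances[others]) &
                     others %in% names(d_n) & !is.na(d_n[others])]
  if (!length(others)) stop("no other patient with complete data", call. = FALSE)
  unname(d_n[patient] + mean(end_distances[others] - d_n[others]))
}

#' Least-squares logarithmic trend fit
#'
#' Fits `d = a * ln(x) + b` by simple linear regression of the distances on
#' `ln(week)`, in closed form.
#'
#' @param weeks Positive week values (at least 2 distinct).
#' @param distances Matching 6MWT distances (m).
#' @return A `log_fit` list: `a` (m per ln-week), `b` (m), `n_points`,
#'   `weeks_used`.
#' @export
#' @examples
#' f <- fit_log(1:6, 10 * log(1:6) + 300)
#' c(f$a, f$b)   # 10, 300
fit_log <- function(weeks, distances) {
  stopifnot(length(weeks) == length(distances))
  ok <- stats::complete.cases(weeks, distances)
  weeks <- weeks[ok]
  distances <- distances[ok]
  if (any(weeks <= 0)) stop("week values must be > 0", call. = FALSE)
  if (length(unique(weeks)) < 2) {
    stop("need at least 2 distinct week values", call. = FALSE)
  }
  lx <- log(weeks)
  a <- stats::cov(lx, distances) / stats::var(lx)
  b <- mean(distances) - a * mean(lx)
  structure(
    list(a = a, b = b, n_points = length(weeks), weeks_used = sort(unique(weeks))),
    class = "log_fit"
  )
}

#' @export
print.log_fit <- function(x, ...) {
  cat(sprintf("<log_fit> d = %.2f * ln(week) + %.2f  (%d points)\n",
              x$a, x$b, x$n_points))
  invisible(x)
}

#' Evaluate a logarithmic trend fit at a week
#'
#' @param fit A `log_fit`.
#' @param week Week to evaluate at (> 0), typically the study-end week.
#' @return Predicted distance (m).
#' @export
predict_log <- function(fit, week = 12) {
  stopifnot(inherits(fit, "log_fit"), week > 0)
  fit$a * log(week) + fit$b
}

app_tests_upto <- function(walktests, week) {
  walktests[walktests$source == "app" & walktests$study_week > 0 &
              walktests$study_week <= week, , drop = FALSE]
}

#' Individual logarithmic-interpolation prediction
#'
#' Fits the patient's own unsupervised 6MWTs up to week `n` with
#' [fit_log()] and extrapolates to the study-end week. Abstains (returns
#' `NA`) when fewer than two distinct test weeks are available, which is
#' always the case at baseline.
#'
#' @param patient Patient id.
#' @param week Week `n`: tests at fractional study weeks in `(0, n]` enter
#'   the fit.
#' @param walktests Walk-test data frame.
#' @param horizon Study-end week to extrapolate to (default 12).
#' @return Predicted end distance (m) or `NA`.
#' @export
predict_log_individual <- function(patient, week, walktests, horizon = 12) {
  own <- app_tests_upto(walktests, week)
  own <- own[own$patient_id == patient, , drop = FALSE]
  if (length(unique(own$study_week)) < 2) return(NA_real_)
  predict_log(fit_log(own$study_week, own$distance_m), horizon)
}

#' Pooled logarithmic-interpolation prediction
#'
#' Assumes all patients improve along a shared logarithmic trend. Each
#' contributing patient's tests up to week `n` are centred by that
#' patient's own mean over those tests, one pooled trend `(a_n, b_n)` is
#' fitted to the centred points, and the prediction for the target patient
#' is `a_n * ln(horizon) + b_n + d_bar_i`, re-adding the patient's own
#' centring mean so the result is an actual distance.
#'
#' @param patient Patient id (needs at least one own test by week `n` to
#'   define `d_bar_i`).
#' @param week Week `n`.
#' @param walktests Walk-test data frame.
#' @param horizon Study-end week (default 12).
#' @param fit_patients Ids contributing to the pooled fit (default: all).
#'   The leave-one-out harness passes everyone but the held-out patient;
#'   the held-out patient's own tests still define their centring mean.
#' @return Predicted end distance (m) or `NA` when the patient has no test
#'   or the pooled fit is underdetermined.
#' @export
predict_log_pooled <- function(patient, week, walktests, horizon = 12,
                               fit_patients = NULL) {
  app <- app_tests_upto(walktests, week)
  own <- app[app$patient_id == patient, , drop = FALSE]
  if (!nrow(own)) return(NA_real_)
  d_bar_i <- mean(own$distance_m)
  pool <- if (is.null(fit_patients)) {
    app
  } else {
    app[app$patient_id %in% unique(c(fit_patients, patient)), , drop = FALSE]
  }
  means <- tapply(pool$distance_m, pool$patient_id, mean)
  centred <- pool$distance_m - as.numeric(means[pool$patient_id])
  if (length(unique(pool$study_week)) < 2) return(NA_real_)
  fit <- fit_log(pool$study_week, centred)
  predict_log(fit, horizon) + d_bar_i
}

#' Candidate feature matrix for the linear-regression predictor
#'
#' One row per patient. Baseline (in-clinic) candidates: numeric-coded sex
#' (female = 0, male = 1), age, height, weight, the subjectively estimated
#' pain-free walking distance, the measured baseline 6MWT distance, the gap
#' between the two (`subjective - measured`), the ratio of the two baseline
#' TUG total times (first / second), and the eight subtask times of both
#' baseline TUG tests. For `week >= 1` three telehealth candidates are
#' added: the mean app-test distance up to week `n`, the week-`n` distance
#' level (with carry-forward), and the logarithmic trend prediction at week
#' `n` (the individual fit, or the pooled fit for patients whose own fit is
#' underdetermined). At week 0 these columns are absent, not imputed.
#'
#' @param dataset A `walk_dataset`.
#' @param week Prediction week `n`.
#' @param horizon Study-end week for the logarithmic feature.
#' @return Data frame of candidate features, rownames = patient ids.
#' @export
build_features <- function(dataset, week, horizon = 12) {
  b <- dataset$baseline
  out <- data.frame(
    sex = as.numeric(b$sex == "male"),
    age = b$age,
    height_m = b$height_m,
    weight_kg = b$weight_kg,
    subjective_painfree_m = b$subjective_painfree_m,
    baseline_6mwt_m = b$baseline_6mwt_m,
    subj_gap_m = b$subjective_painfree_m - b$baseline_6mwt_m,
    row.names = b$patient_id
  )
  if (all(c("tug1_total_time", "tug2_total_time") %in% names(b))) {
    out$tug_ratio <- b$tug1_total_time / b$tug2_total_time
  }
  for (prefix in c("tug1_", "tug2_")) {
    cols <- grep(paste0("^", prefix), names(b), value = TRUE)
    for (col in cols) out[[col]] <- b[[col]]
  }
  if (week >= 1) {
    app <- app_tests_upto(dataset$walktests, week)
    upto <- tapply(app$distance_m, app$patient_id, mean)
    out$mean_dist_upto <- as.numeric(upto[rownames(out)])
    weekly <- aggregate_weekly(dataset)
    out$mean_dist_in_week <- as.numeric(
      weekly_distance_cf(weekly, week)[rownames(out)]
    )
    # trend prediction feature: the patient's own log fit where it is
    # well-posed; the pooled fit otherwise. (The pooled prediction equals
    # the patient's mean test distance plus a cohort constant, so using it
    # throughout would duplicate `mean_dist_upto` up to an affine map.)
    out$log_pred <- vapply(
      rownames(out),
      function(p) {
        v <- predict_log_individual(p, week, dataset$walktests, horizon)
        if (is.na(v)) v <- predict_log_pooled(p, week, dataset$walktests, horizon)
        v
      },
      numeric(1)
    )
  }
  out
}

#' Ordinary least-squares fit
#'
#' Closed-form OLS with an intercept. Rank deficiency is an error naming
#' the collinear columns rather than silently dropping them.
#'
#' @param X Numeric feature matrix or data frame.
#' @param y Response vector.
#' @return A `linreg_fit` list with `intercept` and named `coefficients`.
#' @export
fit_linreg <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < ncol(X) + 1) {
    stop("need at least p + 1 rows for p features", call. = FALSE)
  }
  Xi <- cbind("(Intercept)" = 1, X)
  dec <- qr(Xi)
  if (dec$rank < ncol(Xi)) {
    dropped <- colnames(Xi)[dec$pivot[(dec$rank + 1):ncol(Xi)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(dec, y)
  structure(
    list(intercept = unname(beta[1]), coefficients = beta[-1]),
    class = "linreg_fit"
  )
}

#' Predict from an OLS fit
#'
#' @param object A `linreg_fit`.
#' @param newdata Feature matrix/data frame with the fitted columns.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.linreg_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, names(object$coefficients), drop = FALSE])
  as.numeric(object$intercept + X %*% object$coefficients)
}
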