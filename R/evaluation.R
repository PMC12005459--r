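#' Root mean squared error
#'
#' @param predicted,actual Numeric vectors of equal, non-zero length.
#' @return RMSE in the units of the inputs.
#' @export
rmse <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("length mismatch", call. = FALSE)
  }
  if (!length(predicted)) stop("empty input", call. = FALSE)
  sqrt(mean((predicted - actual)^2))
}

loo_models <- c("baseline", "avg", "log_ind", "log_pool", "linreg")

#' Leave-one-out evaluation of one model at one week
#'
#' Evaluates a predictor of the study-end 6MWT distance under the
#' leave-one-out protocol: for each patient with a measured end distance,
#' any cohort-level fitting (the average-improvement reference set, the
#' pooled logarithmic trend, the regression coefficients) uses only the
#' other patients, while the held-out patient's own telehealth data up to
#' week `n` feed their patient-specific inputs. Patients for whom the model
#' abstains (e.g. too few tests for a log fit) are dropped from the cell.
#' Negative predictions are clamped to zero.
#'
#' @param dataset A `walk_dataset` whose baseline table carries
#'   `end_6mwt_m`.
#' @param model One of `"baseline"`, `"avg"`, `"log_ind"`, `"log_pool"`,
#'   `"linreg"`.
#' @param week Week `n` of prediction (0 = baseline).
#' @param horizon Study-end week (defaults to the dataset's week count).
#' @param linreg_features Feature columns for the `"linreg"` model;
#'   defaults to the four in-clinic features (baseline distance, sex,
#'   subjective-gap, TUG ratio) plus, for `week >= 1`, the three telehealth
#'   features.
#' @return A list with `model`, `week`, `rmse`, `n` (patients evaluated)
#'   and `predictions` (data frame of `patient_id`, `predicted_end_m`,
#'   `actual_end_m`).
#' @export
loo_evaluate <- function(dataset, model, week,
                         horizon = NULL, linreg_features = NULL) {
  model <- match.arg(model, loo_models)
  b <- dataset$baseline
  if (is.null(horizon)) horizon <- dataset_n_weeks(dataset)
  end <- stats::setNames(b$end_6mwt_m, b$patient_id)
  eval_ids <- names(end)[!is.na(end)]
  if (length(eval_ids) < 2) {
    stop("need at least 2 patients with end distances", call. = FALSE)
  }

  weekly <- NULL
  feats <- NULL
  if (model == "avg") weekly <- aggregate_weekly(dataset)
  if (model == "linreg") {
    feats <- build_features(dataset, week, horizon)
    if (is.null(linreg_features)) {
      linreg_features <- intersect(
        c("baseline_6mwt_m", "sex", "subj_gap_m", "tug_ratio",
          "mean_dist_upto", "mean_dist_in_week", "log_pred"),
        names(feats)
      )
    }
    feats <- feats[, linreg_features, drop = FALSE]
  }

  pred <- stats::setNames(rep(NA_real_, length(eval_ids)), eval_ids)
  for (i in eval_ids) {
    pred[i] <- switch(
      model,
      baseline = predict_baseline(b$baseline_6mwt_m[b$patient_id == i]),
      avg = tryCatch(
        predict_avg_improvement(i, week, weekly, end),
        error = function(e) NA_real_
      ),
      log_ind = predict_log_individual(i, week, dataset$walktests, horizon),
      log_pool = predict_log_pooled(i, week, dataset$walktests, horizon,
                                    fit_patients = setdiff(eval_ids, i)),
      linreg = {
        train_ids <- setdiff(eval_ids, i)
        train_ids <- train_ids[stats::complete.cases(feats[train_ids, ,
                                                           drop = FALSE])]
        if (length(train_ids) >= ncol(feats) + 2 &&
            all(stats::complete.cases(feats[i, , drop = FALSE]))) {
          fit <- tryCatch(
            fit_linreg(feats[train_ids, , drop = FALSE], end[train_ids]),
            error = function(e) NULL
          )
          if (is.null(fit)) NA_real_ else {
            predict(fit, feats[i, , drop = FALSE])
          }
        } else {
          NA_real_
        }
      }
    )
  }
  pred <- pmax(pred, 0)
  ok <- !is.na(pred)
  list(
    model = model, week = week,
    rmse = if (any(ok)) rmse(pred[ok], end[names(pred)[ok]]) else NA_real_,
    n = sum(ok),
    predictions = data.frame(
      patient_id = names(pred)[ok],
      predicted_end_m = unname(pred[ok]),
      actual_end_m = unname(end[names(pred)[ok]]),
      stringsAsFactors = FALSE
    )
  )
}

#' Leave-one-out RMSE for every model and week
#'
#' Runs [loo_evaluate()] over the model list and weeks 0 to `n_weeks - 1`.
#' The baseline reference appears only in the week-0 column and the
#' logarithmic models only from week 1, mirroring the structure of a
#' model-by-week RMSE table; absent cells are omitted from the long output
#' (and shown as em-dashes by [format_rmse_table()]).
#'
#' For the regression row the best feature combination of up to
#' `max_features` features is chosen per week by [feature_search()] in
#' `"grid"` mode.
#'
#' @param dataset A `walk_dataset`.
#' @param models Model names (subset of
#'   `c("baseline", "avg", "log_ind", "log_pool", "linreg")`).
#' @param weeks Weeks to evaluate (default `0:(n_weeks - 1)`).
#' @param max_features Feature-subset cap for the regression row.
#' @param candidates Candidate feature columns for the regression row
#'   (default: the in-clinic best-4 candidates plus the telehealth three).
#' @param horizon Study-end week.
#' @return Long data frame: `model`, `week`, `rmse`, `n`.
#' @export
sweep_weeks <- function(dataset, models = loo_models, weeks = NULL,
                        max_features = 4, candidates = NULL, horizon = NULL) {
  models <- match.arg(models, loo_models, several.ok = TRUE)
  n_weeks <- dataset_n_weeks(dataset)
  if (is.null(horizon)) horizon <- n_weeks
  if (is.null(weeks)) weeks <- 0:(n_weeks - 1)
  rows <- list()
  for (model in models) {
    for (wk in weeks) {
      if (model == "baseline" && wk != 0) next
      if (model %in% c("log_ind", "log_pool") && wk == 0) next
      if (model == "linreg") {
        fs <- feature_search(dataset, wk, max_features = max_features,
                             candidates = candidates, mode = "grid",
                             horizon = horizon)
        rows[[length(rows) + 1L]] <- data.frame(
          model = model, week = wk, rmse = fs$best$rmse, n = fs$n_rows,
          stringsAsFactors = FALSE
        )
      } else {
        res <- loo_evaluate(dataset, model, wk, horizon = horizon)
        if (!is.na(res$rmse)) {
          rows[[length(rows) + 1L]] <- data.frame(
            model = model, week = wk, rmse = res$rmse, n = res$n,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format a sweep as a model-by-week table
#'
#' @param sweep Long output of [sweep_weeks()].
#' @param digits Rounding for the RMSE cells.
#' @return Wide data frame, one row per model, one column per week,
#'   abstaining cells shown as `"-"`.
#' @export
format_rmse_table <- function(sweep, digits = 0) {
  weeks <- sort(unique(sweep$week))
  models <- unique(sweep$model)
  out <- data.frame(model = models, stringsAsFactors = FALSE)
  for (wk in weeks) {
    col <- vapply(models, function(m) {
      v <- sweep$rmse[sweep$model == m & sweep$week == wk]
      if (length(v)) format(round(v, digits), nsmall = digits) else "-"
    }, character(1))
    out[[if (wk == 0) "baseline" else paste0("week_", wk)]] <- col
  }
  out
}

# leave-one-out RMSE of an OLS fit on a fixed feature subset; predictions
# clamped at zero like the other predictors
loo_rmse_ols <- function(X, y) {
  n <- nrow(X)
  preds <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fit <- tryCatch(fit_linreg(X[-i, , drop = FALSE], y[-i]),
                    error = function(e) NULL)
    if (is.null(fit)) return(list(rmse = Inf, predictions = preds))
    preds[i] <- predict(fit, X[i, , drop = FALSE])
  }
  preds <- pmax(preds, 0)
  list(rmse = rmse(preds, y), predictions = preds)
}

#' Exhaustive best-subset search for the regression predictor
#'
#' Enumerates all feature subsets of size 1 to `max_features` and scores
#' each by the leave-one-out RMSE of an OLS fit restricted to the subset.
#' Two selection modes are provided. In `"grid"` mode the subset with the
#' lowest LOO RMSE over the whole grid is reported together with its RMSE;
#' because the selection sees all folds, this RMSE is optimistic. In
#' `"honest"` mode the subset is re-selected inside every leave-one-out
#' training fold (by an inner leave-one-out on the remaining patients) and
#' the reported RMSE is computed on the outer held-out predictions only.
#' Ties are broken towards lower RMSE, then fewer features, then the order
#' in which the candidates are listed.
#'
#' @param dataset A `walk_dataset`.
#' @param week Prediction week `n`.
#' @param max_features Largest subset size to consider.
#' @param candidates Candidate feature columns (default: baseline distance,
#'   sex, subjective-gap, TUG ratio, plus the telehealth features for
#'   `week >= 1`).
#' @param mode `"grid"` (pooled-grid selection) or `"honest"` (see Details).
#' @param budget Maximum number of subsets to enumerate; exceeding it is an
#'   error so a mis-specified candidate list fails fast.
#' @param horizon Study-end week.
#' @return A list with `mode`, `per_k` (best subset and RMSE per subset
#'   size), `best` (overall best: `features`, `k`, `rmse`), `n_subsets`
#'   (subsets scored), `n_rows` (patients entering the search) and, in
#'   honest mode, `honest_rmse` plus the per-fold selections.
#' @export
feature_search <- function(dataset, week, max_features = 4,
                           candidates = NULL, mode = c("grid", "honest"),
                           budget = 20000, horizon = NULL) {
  mode <- match.arg(mode)
  if (is.null(horizon)) horizon <- dataset_n_weeks(dataset)
  feats <- build_features(dataset, week, horizon)
  if (is.null(candidates)) {
    candidates <- intersect(
      c("baseline_6mwt_m", "sex", "subj_gap_m", "tug_ratio",
        "mean_dist_upto", "mean_dist_in_week", "log_pred"),
      names(feats)
    )
  }
  missing_cand <- setdiff(candidates, names(feats))
  if (length(missing_cand)) {
    stop("unknown candidate feature(s): ",
         paste(missing_cand, collapse = ", "), call. = FALSE)
  }
  max_features <- min(max_features, length(candidates))
  n_subsets <- sum(choose(length(candidates), seq_len(max_features)))
  if (n_subsets > budget) {
    stop(sprintf(
      "subset search would score %d subsets, above the budget of %d",
      n_subsets, budget), call. = FALSE)
  }

  b <- dataset$baseline
  end <- stats::setNames(b$end_6mwt_m, b$patient_id)
  X_all <- feats[, candidates, drop = FALSE]
  keep <- stats::complete.cases(X_all) & !is.na(end[rownames(X_all)])
  X_all <- as.matrix(X_all[keep, , drop = FALSE])
  y <- unname(end[rownames(X_all)])
  if (nrow(X_all) < max_features + 2) {
    stop("too few complete patients for the requested subset size",
         call. = FALSE)
  }

  # improvements below this (in metres) count as ties, resolved towards
  # fewer features and earlier candidate order
  tie_tol <- 1e-8
  select_best <- function(X, y) {
    best <- list(rmse = Inf, features = NULL, k = NA_integer_)
    per_k <- vector("list", max_features)
    count <- 0L
    for (k in seq_len(max_features)) {
      combos <- utils::combn(candidates, k, simplify = FALSE)
      best_k <- list(rmse = Inf, features = NULL)
      for (cs in combos) {
        count <- count + 1L
        sc <- loo_rmse_ols(X[, cs, drop = FALSE], y)$rmse
        if (sc < best_k$rmse - tie_tol) best_k <- list(rmse = sc, features = cs)
        if (sc < best$rmse - tie_tol) best <- list(rmse = sc, features = cs, k = k)
      }
      per_k[[k]] <- data.frame(
        k = k,
        features = paste(best_k$features, collapse = "+"),
        rmse = best_k$rmse,
        stringsAsFactors = FALSE
      )
    }
    list(best = best, per_k = do.call(rbind, per_k), count = count)
  }

  sel <- select_best(X_all, y)
  out <- list(
    mode = mode, per_k = sel$per_k, best = sel$best,
    n_subsets = sel$count, n_rows = nrow(X_all)
  )

  if (mode == "honest") {
    n <- nrow(X_all)
    preds <- rep(NA_real_, n)
    fold_features <- character(n)
    for (i in seq_len(n)) {
      inner <- select_best(X_all[-i, , drop = FALSE], y[-i])
      cs <- inner$best$features
      fold_features[i] <- paste(cs, collapse = "+")
      fit <- fit_linreg(X_all[-i, cs, drop = FALSE], y[-i])
      preds[i] <- predict(fit, X_all[i, cs, drop = FALSE])
    }
    preds <- pmax(preds, 0)
    out$honest_rmse <- rmse(preds, y)
    out$fold_features <- fold_features
  }
  out
}
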