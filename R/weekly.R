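#' Aggregate a cohort dataset to weekly means
#'
#' Collapses the raw records to one row per patient and study week: the
#' arithmetic mean of all 6MWT distances whose test week equals the week
#' (clinic visits at weeks 0 and `n_weeks`, app tests at the ceiling of
#' their fractional study week), and the means of the daily signals whose
#' day falls in the week (`floor(study_day / 7)`). Weeks with no data stay
#' missing (`NA`) and are never zero-filled; `n_tests` counts all walk
#' tests, clinic and app, in the week.
#'
#' @param dataset A `walk_dataset`.
#' @return A data frame with columns `patient_id`, `week`,
#'   `mean_distance_m`, `mean_pain`, `mean_steps`, `mean_wellbeing`,
#'   `n_tests`, covering the full patient-by-week grid from week 0 to
#'   `n_weeks`.
#' @export
#' @examples
#' ds <- generate_cohort(cohort_config(n_patients = 3, seed = 7))
#' wk <- aggregate_weekly(ds)
#' subset(wk, patient_id == "P001")
aggregate_weekly <- function(dataset) {
  stopifnot(inherits(dataset, "walk_dataset"))
  n_weeks <- dataset_n_weeks(dataset)
  patients <- dataset$baseline$patient_id
  grid <- expand.grid(
    patient_id = patients, week = 0:n_weeks,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- grid[order(grid$patient_id, grid$week), , drop = FALSE]
  key <- function(p, w) paste(p, w, sep = "\r")
  gk <- key(grid$patient_id, grid$week)

  w <- dataset$walktests
  wwk <- test_week(w$study_week, w$source)
  tk <- key(w$patient_id, wwk)
  mean_by <- function(values, keys) {
    ok <- !is.na(values)
    if (!any(ok)) return(stats::setNames(numeric(0), character(0)))
    tapply(values[ok], keys[ok], mean)
  }
  dist_mean <- mean_by(w$distance_m, tk)
  n_tests <- table(tk)

  d <- dataset$daily
  dk <- key(d$patient_id, d$study_day %/% 7L)
  pain_mean <- mean_by(d$pain, dk)
  steps_mean <- mean_by(d$steps, dk)
  wb_mean <- mean_by(d$wellbeing, dk)

  pick <- function(tab, keys) {
    out <- as.numeric(tab[keys])
    out[!keys %in% names(tab)] <- NA_real_
    out
  }
  grid$mean_distance_m <- pick(dist_mean, gk)
  grid$mean_pain <- pick(pain_mean, gk)
  grid$mean_steps <- pick(steps_mean, gk)
  grid$mean_wellbeing <- pick(wb_mean, gk)
  nt <- as.integer(n_tests[gk])
  nt[is.na(nt)] <- 0L
  grid$n_tests <- nt
  rownames(grid) <- NULL
  grid
}

#' Normalise a weekly series by the patient-individual mean
#'
#' For plotting and trend comparison across patients, each patient's weekly
#' values are related to that patient's own mean over all weeks: divided by
#' it (`mode = "ratio"`, the default for distances, so a flat series maps to
#' 1) or mean-centred by subtraction (`mode = "center"`, the default for
#' pain scores). Missing weeks stay missing; a patient with no non-missing
#' value for the signal is skipped with a warning.
#'
#' @param series A weekly series from [aggregate_weekly()].
#' @param signal Column to normalise, e.g. `"mean_distance_m"`.
#' @param mode `"ratio"` or `"center"`; when `NULL`, ratio is used for
#'   distance-like signals and centring for everything else.
#' @return `series` with an added `normalized` column.
#' @export
normalize_by_patient_mean <- function(series,
                                      signal = "mean_distance_m",
                                      mode = NULL) {
  stopifnot(signal %in% names(series))
  if (is.null(mode)) {
    mode <- if (grepl("distance", signal)) "ratio" else "center"
  }
  mode <- match.arg(mode, c("ratio", "center"))
  out <- series
  out$normalized <- NA_real_
  for (pid in unique(series$patient_id)) {
    idx <- which(series$patient_id == pid)
    vals <- series[[signal]][idx]
    if (all(is.na(vals))) {
      warning("patient ", pid, " has no non-missing ", signal,
              "; skipped", call. = FALSE)
      next
    }
    m <- mean(vals, na.rm = TRUE)
    out$normalized[idx] <- if (mode == "ratio") vals / m else vals - m
  }
  out
}

#' Weekly distance with carry-forward
#'
#' The week-`n` 6MWT level `d_n_i` used by the prediction models: the
#' patient's mean distance in week `n`, or, when week `n` has no test, the
#' most recent earlier weekly mean. `NA` when the patient has no test at all
#' up to week `n`.
#'
#' @param weekly A weekly series from [aggregate_weekly()].
#' @param week Week index `n` (0-based).
#' @return Named numeric vector of carried-forward distances, one entry per
#'   patient present in `weekly`.
#' @export
weekly_distance_cf <- function(weekly, week) {
  patients <- unique(weekly$patient_id)
  out <- stats::setNames(rep(NA_real_, length(patients)), patients)
  sub <- weekly[weekly$week <= week & !is.na(weekly$mean_distance_m), ,
                drop = FALSE]
  if (nrow(sub)) {
    sub <- sub[order(sub$patient_id, sub$week), , drop = FALSE]
    last <- tapply(sub$mean_distance_m, sub$patient_id, function(v) v[length(v)])
    out[names(last)] <- as.numeric(last)
  }
  out
}
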