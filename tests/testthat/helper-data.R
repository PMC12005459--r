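# Hand-built fixtures used across test files.

toy_baseline <- function(ids, end = NULL, baseline = NULL) {
  n <- length(ids)
  data.frame(
    patient_id = ids,
    sex = rep(c("female", "male"), length.out = n),
    age = rep(60, n),
    height_m = rep(1.7, n),
    weight_kg = rep(75, n),
    subjective_painfree_m = rep(80, n),
    fontaine = rep("IIb", n),
    baseline_6mwt_m = if (is.null(baseline)) rep(300, n) else baseline,
    end_6mwt_m = if (is.null(end)) rep(NA_real_, n) else end,
    stringsAsFactors = FALSE
  )
}

toy_dataset <- function(baseline, walktests, daily = NULL) {
  if (is.null(daily)) {
    daily <- data.frame(
      patient_id = character(0), study_day = integer(0),
      steps = integer(0), pain = integer(0), wellbeing = integer(0)
    )
  }
  structure(
    list(baseline = baseline, walktests = walktests, daily = daily,
         truth = NULL, config = NULL),
    class = "walk_dataset"
  )
}

# cohort in which every patient follows d(x) = a * ln(x) + b exactly and
# tests fall on the same fixed weeks; end_6mwt_m is the exact trajectory end
exact_log_cohort <- function(a, b, test_weeks = 1:6, n_weeks = 12) {
  ids <- sprintf("P%02d", seq_along(b))
  if (length(a) == 1) a <- rep(a, length(b))
  tests <- do.call(rbind, lapply(seq_along(ids), function(i) {
    data.frame(
      patient_id = ids[i],
      study_week = c(0, test_weeks, n_weeks),
      distance_m = c(b[i], a[i] * log(test_weeks) + b[i],
                     a[i] * log(n_weeks) + b[i]),
      source = c("clinic", rep("app", length(test_weeks)), "clinic"),
      stringsAsFactors = FALSE
    )
  }))
  bl <- toy_baseline(ids, end = a * log(n_weeks) + b, baseline = b)
  ds <- toy_dataset(bl, tests)
  ds$config <- list(n_weeks = n_weeks)
  ds$truth <- data.frame(patient_id = ids, a = a, b = b,
                         end_distance_m = a * log(n_weeks) + b)
  ds
}

# walk-test table with a given number of app tests per patient
make_adherence_tests <- function(counts) {
  do.call(rbind, lapply(seq_along(counts), function(i) {
    n <- counts[i]
    data.frame(
      patient_id = sprintf("P%02d", i),
      study_week = c(0, seq_len(n) / 2, 12),
      distance_m = 400,
      source = c("clinic", rep("app", n), "clinic")
    )
  }))
}
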