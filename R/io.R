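#' Load a cohort dataset from CSV files
#'
#' Reads `baseline.csv`, `walktests.csv` and `daily.csv` from `dir`,
#' validates every row against the schema invariants (scale bounds, positive
#' distances, referential integrity of `patient_id`), and returns a
#' `walk_dataset`. A `truth.csv` file, when present, is attached as latent
#' ground truth. Violations are reported with the offending file and row
#' numbers.
#'
#' @param dir Directory containing the CSV files.
#' @return A `walk_dataset` (see [generate_cohort()]).
#' @export
load_dataset <- function(dir) {
  need <- c("baseline.csv", "walktests.csv", "daily.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rd <- function(name) {
    utils::read.csv(file.path(dir, name), stringsAsFactors = FALSE,
                    na.strings = c("", "NA"))
  }
  baseline <- rd("baseline.csv")
  walktests <- rd("walktests.csv")
  daily <- rd("daily.csv")
  truth <- if (file.exists(file.path(dir, "truth.csv"))) rd("truth.csv") else NULL
  cfg_path <- file.path(dir, "config.yaml")
  config <- if (file.exists(cfg_path)) yaml::read_yaml(cfg_path) else NULL

  ds <- structure(
    list(baseline = baseline, walktests = walktests, daily = daily,
         truth = truth, config = config),
    class = "walk_dataset"
  )
  validate_dataset(ds)
  ds
}

#' Validate a cohort dataset against its schema invariants
#'
#' @param dataset A `walk_dataset`.
#' @return Invisibly, the dataset; stops with row-level diagnostics on the
#'   first batch of violations found.
#' @export
validate_dataset <- function(dataset) {
  b <- dataset$baseline
  w <- dataset$walktests
  d <- dataset$daily
  problems <- character(0)
  add <- function(file, rows, what) {
    if (length(rows)) {
      sprintf("%s row %s: %s", file, paste(rows, collapse = ","), what)
    } else {
      character(0)
    }
  }

  need_b <- c("patient_id", "sex", "age", "baseline_6mwt_m")
  need_w <- c("patient_id", "study_week", "distance_m", "source")
  need_d <- c("patient_id", "study_day", "steps", "pain", "wellbeing")
  for (spec in list(list(b, need_b, "baseline.csv"),
                    list(w, need_w, "walktests.csv"),
                    list(d, need_d, "daily.csv"))) {
    miss <- spec[[2]][!spec[[2]] %in% names(spec[[1]])]
    if (length(miss)) {
      stop(spec[[3]], ": missing column(s) ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }

  bad <- which(!is.na(b$age) & (b$age < 18 | b$age > 80))
  problems <- c(problems, add("baseline.csv", bad, "age outside [18, 80]"))
  for (col in c("baseline_6mwt_m", "end_6mwt_m", "subjective_painfree_m")) {
    if (col %in% names(b)) {
      bad <- which(!is.na(b[[col]]) & b[[col]] <= 0)
      problems <- c(problems, add("baseline.csv", bad,
                                  paste(col, "must be > 0")))
    }
  }
  if (anyDuplicated(b$patient_id)) {
    problems <- c(problems,
                  add("baseline.csv", which(duplicated(b$patient_id)),
                      "duplicate patient_id"))
  }

  bad <- which(is.na(w$distance_m) | w$distance_m <= 0 | w$distance_m >= 1000)
  problems <- c(problems, add("walktests.csv", bad,
                              "distance_m outside (0, 1000)"))
  bad <- which(is.na(w$study_week) | w$study_week < 0)
  problems <- c(problems, add("walktests.csv", bad, "negative study_week"))
  bad <- which(!w$source %in% c("clinic", "app"))
  problems <- c(problems, add("walktests.csv", bad,
                              "source must be 'clinic' or 'app'"))
  final_wk <- suppressWarnings(max(w$study_week[w$source == "clinic"], 0))
  bad <- which(w$source == "clinic" & !(w$study_week == 0 | w$study_week == final_wk))
  problems <- c(problems, add("walktests.csv", bad,
                              "clinic tests only at week 0 or the final week"))
  bad <- which(!w$patient_id %in% b$patient_id)
  problems <- c(problems, add("walktests.csv", bad, "unknown patient_id"))

  bad <- which(!is.na(d$pain) & (d$pain < 0 | d$pain > 10 |
                                   d$pain != round(d$pain)))
  problems <- c(problems, add("daily.csv", bad,
                              "pain outside the 0-10 integer scale"))
  bad <- which(!is.na(d$wellbeing) & !d$wellbeing %in% 1:3)
  problems <- c(problems, add("daily.csv", bad, "wellbeing not in {1,2,3}"))
  bad <- which(!is.na(d$steps) & d$steps < 0)
  problems <- c(problems, add("daily.csv", bad, "negative steps"))
  bad <- which(is.na(d$study_day) | d$study_day < 0 |
                 d$study_day != round(d$study_day))
  problems <- c(problems, add("daily.csv", bad,
                              "study_day must be a non-negative integer"))
  bad <- which(!d$patient_id %in% b$patient_id)
  problems <- c(problems, add("daily.csv", bad, "unknown patient_id"))

  if (length(problems)) {
    stop("dataset validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(dataset)
}

#' Number of program weeks represented in a dataset
#'
#' Inferred as the largest week index carried by either the walk tests or
#' the daily records; the stored generator configuration takes precedence
#' when available.
#'
#' @param dataset A `walk_dataset`.
#' @return Integer number of weeks.
#' @export
dataset_n_weeks <- function(dataset) {
  if (!is.null(dataset$config$n_weeks)) {
    return(as.integer(dataset$config$n_weeks))
  }
  wk_tests <- if (nrow(dataset$walktests)) {
    max(ceiling(dataset$walktests$study_week))
  } else {
    0L
  }
  wk_daily <- if (nrow(dataset$daily)) {
    max(dataset$daily$study_day %/% 7L)
  } else {
    0L
  }
  as.integer(max(wk_tests, wk_daily))
}

# Week assignment for walk tests: clinic visits sit exactly on week 0 or the
# final week; an app test at fractional study week x belongs to week
# ceiling(x), so tests during the first program week ((0, 1]) count as week 1.
test_week <- function(study_week, source) {
  ifelse(source == "clinic", round(study_week), ceiling(study_week))
}
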