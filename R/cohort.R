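#' Configuration for a synthetic telehealth walking-program cohort
#'
#' Builds and validates the parameter set that drives [generate_cohort()].
#' Defaults are calibrated to the published summary statistics of a 12-week
#' home-based structured-walking-training program for Fontaine stage II
#' peripheral arterial disease patients: daily pain declining in expectation
#' from 4.67 to 3.60 on the 0-10 scale, mean daily steps 4176.58
#' (SD 2742.73), a pooled same-day pain vs. 6MWT-distance correlation of
#' about -0.39, a well-being split of roughly 2.6/43.0/54.5 percent
#' (bad/medium/good), and 6MWT distances that improve along a logarithmic
#' trend `a * ln(week) + b` saturating towards a study-end mean near 425 m.
#'
#' @param n_patients Number of patients (positive integer).
#' @param n_weeks Program length in weeks (integer, >= 2). Default 12.
#' @param seed Integer seed for the root random generator.
#' @param traj_a_mean,traj_a_sd Mean and SD (m per ln-week) of the
#'   patient-level logarithmic improvement slope `a`.
#' @param traj_b_mean,traj_b_sd Mean and SD (m) of the trajectory intercept
#'   `b`, i.e. the expected distance at week 1 (and the baseline level).
#' @param meas_noise_sd Measurement noise SD (m) of a single 6MWT.
#' @param pain_base_mean,pain_base_sd Cohort mean and between-patient SD of
#'   the week-0 daily pain score (0-10 scale).
#' @param pain_end_mean Cohort mean daily pain in the final study week.
#' @param pain_noise_sd Within-patient day-to-day pain SD (score units).
#' @param steps_mean,steps_sd Cohort mean and SD of daily step counts; steps
#'   are drawn log-normally so the configured mean is matched exactly in
#'   expectation despite non-negativity.
#' @param pain_distance_corr Target pooled same-day correlation between the
#'   reported pain score and the 6MWT distance, in `[-1, 1]`.
#' @param tests_per_week_rate Expected number of app-based 6MWTs per week for
#'   a fully adherent patient (>= 1 guarantees one test every week).
#' @param p_full_adherence Probability that a patient follows the
#'   once-per-week test recommendation in every week.
#' @param wellbeing_cutpoints Two strictly increasing thresholds on the
#'   standard-normal latent daily state separating bad/medium/good
#'   well-being. Defaults reproduce the printed counts 41/686/870 of 1597.
#' @param p_report_pain,p_report_wellbeing,p_report_steps Daily probability
#'   that the respective signal is submitted.
#'
#' @return An object of class `cohort_config` (a named list).
#' @seealso [generate_cohort()]
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 19, seed = 1)
#' cfg$pain_base_mean
cohort_config <- function(n_patients,
                          n_weeks = 12L,
                          seed = 1L,
                          traj_a_mean = 40,
                          traj_a_sd = 15,
                          traj_b_mean = 330,
                          traj_b_sd = 80,
                          meas_noise_sd = 25,
                          pain_base_mean = 4.67,
                          pain_base_sd = 1.90,
                          pain_end_mean = 3.60,
                          pain_noise_sd = 2.0,
                          steps_mean = 4176.58,
                          steps_sd = 2742.73,
                          pain_distance_corr = -0.39,
                          tests_per_week_rate = 1.45,
                          p_full_adherence = 11 / 19,
                          wellbeing_cutpoints = stats::qnorm(c(41, 727) / 1597),
                          p_report_pain = 0.92,
                          p_report_wellbeing = 0.92,
                          p_report_steps = 0.95) {
  cfg <- list(
    n_patients = n_patients, n_weeks = n_weeks, seed = seed,
    traj_a_mean = traj_a_mean, traj_a_sd = traj_a_sd,
    traj_b_mean = traj_b_mean, traj_b_sd = traj_b_sd,
    meas_noise_sd = meas_noise_sd,
    pain_base_mean = pain_base_mean, pain_base_sd = pain_base_sd,
    pain_end_mean = pain_end_mean, pain_noise_sd = pain_noise_sd,
    steps_mean = steps_mean, steps_sd = steps_sd,
    pain_distance_corr = pain_distance_corr,
    tests_per_week_rate = tests_per_week_rate,
    p_full_adherence = p_full_adherence,
    wellbeing_cutpoints = wellbeing_cutpoints,
    p_report_pain = p_report_pain,
    p_report_wellbeing = p_report_wellbeing,
    p_report_steps = p_report_steps
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(is.list(cfg))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(cfg$n_patients) || cfg$n_patients < 1 ||
      cfg$n_patients != round(cfg$n_patients)) {
    stop("`n_patients` must be a positive integer", call. = FALSE)
  }
  if (!num1(cfg$n_weeks) || cfg$n_weeks < 2 ||
      cfg$n_weeks != round(cfg$n_weeks)) {
    stop("`n_weeks` must be an integer >= 2", call. = FALSE)
  }
  if (!num1(cfg$seed)) stop("`seed` must be a single number", call. = FALSE)
  for (sd_field in c("traj_a_sd", "traj_b_sd", "meas_noise_sd",
                     "pain_base_sd", "pain_noise_sd", "steps_sd",
                     "tests_per_week_rate")) {
    if (!num1(cfg[[sd_field]]) || cfg[[sd_field]] < 0) {
      stop(sprintf("`%s` must be a non-negative number", sd_field),
           call. = FALSE)
    }
  }
  for (p_field in c("p_full_adherence", "p_report_pain",
                    "p_report_wellbeing", "p_report_steps")) {
    p <- cfg[[p_field]]
    if (!num1(p) || p < 0 || p > 1) {
      stop(sprintf("`%s` must be a probability in [0, 1]", p_field),
           call. = FALSE)
    }
  }
  if (!num1(cfg$pain_distance_corr) || abs(cfg$pain_distance_corr) > 1) {
    stop("`pain_distance_corr` must lie in [-1, 1]", call. = FALSE)
  }
  cp <- cfg$wellbeing_cutpoints
  if (!is.numeric(cp) || length(cp) != 2L || !all(is.finite(cp)) ||
      diff(cp) <= 0) {
    stop("`wellbeing_cutpoints` must be two strictly increasing numbers",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d patients, %d weeks, seed %d\n",
              x$n_patients, x$n_weeks, as.integer(x$seed)))
  cat(sprintf("  trajectory a ~ N(%.1f, %.1f), b ~ N(%.1f, %.1f), 6MWT noise SD %.1f m\n",
              x$traj_a_mean, x$traj_a_sd, x$traj_b_mean, x$traj_b_sd,
              x$meas_noise_sd))
  cat(sprintf("  pain %.2f -> %.2f (between-SD %.2f, daily SD %.2f); steps %.0f (SD %.0f)\n",
              x$pain_base_mean, x$pain_end_mean, x$pain_base_sd,
              x$pain_noise_sd, x$steps_mean, x$steps_sd))
  cat(sprintf("  target pain~distance corr %.2f; full adherence p = %.2f\n",
              x$pain_distance_corr, x$p_full_adherence))
  invisible(x)
}

# Per-patient sub-seed: deterministic arithmetic stream so patient i's data
# are unchanged when n_patients changes. Kept below 2^31 - 1.
patient_seed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) + i * 104729) %% (2^31 - 1))
}

# Expected reported pain for a latent N(mu, sigma) rounded to the nearest
# integer and bounded to the 0-10 scale.
expected_reported_pain <- function(mu, sigma) {
  k <- 1:9
  e <- 10 * (1 - stats::pnorm(9.5, mu, sigma))
  for (ki in k) {
    e <- e + ki * (stats::pnorm(ki + 0.5, mu, sigma) -
                     stats::pnorm(ki - 0.5, mu, sigma))
  }
  e
}

# Inverse of expected_reported_pain() in mu, as an interpolating function.
# Used so the expected *reported* score equals the configured trajectory
# despite rounding and the bounded scale.
pain_mean_inverter <- function(sigma) {
  grid <- seq(-6, 16, by = 0.02)
  ev <- expected_reported_pain(grid, sigma)
  stats::approxfun(ev, grid, rule = 2)
}

# Derived coupling coefficients giving (approximately) the configured pooled
# same-day pain~distance correlation. The covariance budget is split between
# a patient-level component (sicker patients: more pain, shorter distances)
# and a day-level component through the shared latent daily state.
cohort_couplings <- function(cfg) {
  gamma_d <- cfg$meas_noise_sd        # daily-state loading on 6MWT distance, m
  sd_pain <- sqrt(cfg$pain_base_sd^2 + cfg$pain_noise_sd^2)
  # ln(test week) for test times uniform on (0, n_weeks] has variance exactly 1
  e_ln <- log(cfg$n_weeks) - 1
  var_dist <- cfg$traj_b_sd^2 + cfg$traj_a_mean^2 +
    cfg$traj_a_sd^2 * (1 + e_ln^2) + gamma_d^2 + cfg$meas_noise_sd^2
  cov_needed <- cfg$pain_distance_corr * sd_pain * sqrt(var_dist)
  cov_day <- sign(cov_needed) *
    min(0.5 * cfg$pain_noise_sd * gamma_d, abs(cov_needed))
  lambda_p <- if (gamma_d > 0) cov_day / gamma_d else 0
  lambda_p <- sign(lambda_p) * min(abs(lambda_p), cfg$pain_noise_sd)
  denom <- cfg$pain_base_sd * cfg$traj_b_sd
  c_b <- if (denom > 0) (cov_needed - cov_day) / denom else 0
  c_b <- max(-0.97, min(0.97, c_b))

  # Daily step counts are log-normal with the configured mean and SD; the
  # log-scale variance is split between patient level, daily state and
  # residual in fixed proportions (0.34 / 0.11 / 0.55).
  sigma2_log <- log(1 + (cfg$steps_sd / cfg$steps_mean)^2)
  list(
    gamma_d = gamma_d, lambda_p = lambda_p, c_b = c_b,
    pain_resid_sd = sqrt(max(cfg$pain_noise_sd^2 - lambda_p^2, 0)),
    steps_mu_log = log(cfg$steps_mean) - sigma2_log / 2,
    steps_sd_patient = sqrt(0.34 * sigma2_log),
    steps_sd_state = sqrt(0.11 * sigma2_log),
    steps_sd_resid = sqrt(0.55 * sigma2_log)
  )
}

# Reference medians (s) used to shape synthetic timed-up-and-go subtask
# times; derived quantities (walk/mobility/total) are sums of subtasks.
tug_subtask_base <- c(
  stand_up = 2.67, walk_forward = 1.95, turnaround = 1.82,
  walk_back = 2.09, sit_down = 2.21
)

make_tug_record <- function(frailty, factor = 1) {
  st <- tug_subtask_base * frailty * factor * exp(stats::rnorm(5, 0, 0.08))
  c(
    stand_up = unname(st["stand_up"]),
    walk_forward = unname(st["walk_forward"]),
    turnaround = unname(st["turnaround"]),
    walk_back = unname(st["walk_back"]),
    sit_down = unname(st["sit_down"]),
    total_walk_time = unname(st["walk_forward"] + st["turnaround"] +
                               st["walk_back"]),
    mobility_time = unname(st["stand_up"] + st["sit_down"]),
    total_time = unname(sum(st))
  )
}

#' Generate a synthetic telehealth walking-program cohort
#'
#' Simulates per-patient data with the statistical structure the downstream
#' analyses assume. Each patient `i` carries a latent 6MWT trajectory
#' `d_i(x) = a_i * ln(x) + b_i` over study weeks `x` in `(0, n_weeks]`;
#' supervised clinic tests are recorded at week 0 (at the trajectory level
#' `b_i`, i.e. `x` clamped to 1) and at week `n_weeks`; unsupervised app
#' tests fall on random days during the program. Daily pain, steps and
#' 3-level well-being are coupled through one standard-normal latent "daily
#' state" per patient-day, so that good days show more steps, longer test
#' distances, better well-being and less pain, reproducing the signs and
#' approximate magnitudes of the published cross-signal correlations.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `walk_dataset`: a list with data frames
#'   `baseline`, `walktests`, `daily`, `truth` and the `config`. `truth`
#'   holds each patient's latent `a`, `b` and exact end distance
#'   `a * ln(n_weeks) + b` for recovery tests.
#' @export
#' @examples
#' ds <- generate_cohort(cohort_config(n_patients = 5, seed = 42))
#' head(ds$walktests)
generate_cohort <- function(config) {
  validate_cohort_config(config)
  cfg <- config
  cpl <- cohort_couplings(cfg)
  n_days <- 7L * cfg$n_weeks + 7L   # daily reporting covers weeks 0..n_weeks
  days <- seq_len(n_days) - 1L

  invert_pain <- if (cfg$pain_noise_sd > 0) {
    pain_mean_inverter(cfg$pain_noise_sd)
  } else {
    NULL
  }
  # pain trajectory anchored at the mid-days of week 0 and the final week,
  # so the expected weekly means hit the configured endpoints
  pain_slope_days <- 7 * cfg$n_weeks
  trend_frac <- (days - 3) / pain_slope_days

  baseline_rows <- vector("list", cfg$n_patients)
  test_rows <- vector("list", cfg$n_patients)
  daily_rows <- vector("list", cfg$n_patients)
  truth_rows <- vector("list", cfg$n_patients)

  for (i in seq_len(cfg$n_patients)) {
    set.seed(patient_seed(cfg$seed, i))
    pid <- sprintf("P%03d", i)

    u_i <- stats::rnorm(1)                     # fitness latent (higher = fitter)
    b_i <- cfg$traj_b_mean + cfg$traj_b_sd * u_i
    a_i <- cfg$traj_a_mean + cfg$traj_a_sd * stats::rnorm(1)
    p_i <- cfg$pain_base_mean + cfg$pain_base_sd *
      (cpl$c_b * u_i + sqrt(1 - cpl$c_b^2) * stats::rnorm(1))
    nu_i <- stats::rnorm(1)                    # step-level patient effect
    adherent <- stats::runif(1) < cfg$p_full_adherence
    q_i <- stats::runif(1, 0.3, 1)             # weekly test prob if non-adherent
    frailty_i <- exp(-0.15 * u_i + 0.10 * stats::rnorm(1))

    # --- demographics & in-clinic record ---------------------------------
    male <- stats::runif(1) < 0.65
    age <- round(min(80, max(18, stats::rnorm(1, 63.05, 6.55))))
    height <- if (male) stats::rnorm(1, 1.76, 0.05) else stats::rnorm(1, 1.65, 0.03)
    weight <- if (male) stats::rnorm(1, 81.67, 11.95) else stats::rnorm(1, 70.14, 9.5)
    subj <- max(10, stats::rnorm(1, 78.75, 41.04))
    tug1 <- make_tug_record(frailty_i)
    tug2 <- make_tug_record(frailty_i)
    imp_i <- exp(stats::rnorm(1, log(0.93), 0.06))  # end-of-study TUG speed-up
    tug_end <- make_tug_record(frailty_i, factor = imp_i)

    d0 <- b_i + stats::rnorm(1, 0, cfg$meas_noise_sd)
    d_end <- a_i * log(cfg$n_weeks) + b_i + stats::rnorm(1, 0, cfg$meas_noise_sd)
    d0 <- min(max(d0, 1), 999)
    d_end <- min(max(d_end, 1), 999)

    # --- daily signals ----------------------------------------------------
    z <- stats::rnorm(n_days)                  # latent daily state
    pain_target <- p_i + (cfg$pain_end_mean - cfg$pain_base_mean) * trend_frac
    if (is.null(invert_pain)) {
      pain_lat <- pain_target
    } else {
      pain_lat <- invert_pain(pmin(pmax(pain_target, 0.05), 9.95)) +
        cpl$lambda_p * z + cpl$pain_resid_sd * stats::rnorm(n_days)
    }
    pain <- pmin(pmax(round(pain_lat), 0), 10)
    steps <- round(exp(cpl$steps_mu_log + cpl$steps_sd_patient * nu_i +
                         cpl$steps_sd_state * z +
                         cpl$steps_sd_resid * stats::rnorm(n_days)))
    wellbeing <- 1L + (z > cfg$wellbeing_cutpoints[1]) +
      (z > cfg$wellbeing_cutpoints[2])
    pain[stats::runif(n_days) > cfg$p_report_pain] <- NA
    wellbeing[stats::runif(n_days) > cfg$p_report_wellbeing] <- NA
    steps[stats::runif(n_days) > cfg$p_report_steps] <- NA

    # --- app-based walk tests --------------------------------------------
    extra_rate <- max(cfg$tests_per_week_rate - 1, 0)
    test_days <- integer(0)
    for (w in seq_len(cfg$n_weeks)) {
      n_w <- if (adherent) {
        1L + stats::rpois(1, extra_rate)
      } else {
        stats::rbinom(1, 1, q_i)
      }
      n_w <- min(n_w, 7L)
      if (n_w > 0) {
        wk_days <- (7L * (w - 1L) + 1L):(7L * w)
        test_days <- c(test_days, sort(sample(wk_days, n_w)))
      }
    }
    x_test <- test_days / 7
    d_test <- a_i * log(x_test) + b_i + cpl$gamma_d * z[test_days + 1L] +
      stats::rnorm(length(test_days), 0, cfg$meas_noise_sd)
    d_test <- pmin(pmax(d_test, 1), 999)

    baseline_rows[[i]] <- data.frame(
      patient_id = pid, sex = if (male) "male" else "female",
      age = age, height_m = round(height, 2), weight_kg = round(weight, 1),
      subjective_painfree_m = round(subj, 1), fontaine = "IIb",
      baseline_6mwt_m = d0, end_6mwt_m = d_end,
      t(stats::setNames(tug1, paste0("tug1_", names(tug1)))),
      t(stats::setNames(tug2, paste0("tug2_", names(tug2)))),
      t(stats::setNames(tug_end, paste0("tug_end_", names(tug_end)))),
      stringsAsFactors = FALSE
    )
    test_rows[[i]] <- data.frame(
      patient_id = pid,
      study_week = c(0, x_test, cfg$n_weeks),
      distance_m = c(d0, d_test, d_end),
      source = c("clinic", rep("app", length(x_test)), "clinic"),
      stringsAsFactors = FALSE
    )
    daily_rows[[i]] <- data.frame(
      patient_id = pid, study_day = days,
      steps = as.integer(steps), pain = as.integer(pain),
      wellbeing = as.integer(wellbeing), stringsAsFactors = FALSE
    )
    truth_rows[[i]] <- data.frame(
      patient_id = pid, a = a_i, b = b_i,
      end_distance_m = a_i * log(cfg$n_weeks) + b_i,
      stringsAsFactors = FALSE
    )
  }

  structure(
    list(
      baseline = do.call(rbind, baseline_rows),
      walktests = do.call(rbind, test_rows),
      daily = do.call(rbind, daily_rows),
      truth = do.call(rbind, truth_rows),
      config = cfg
    ),
    class = "walk_dataset"
  )
}

#' @export
print.walk_dataset <- function(x, ...) {
  cat("<walk_dataset>\n")
  cat(sprintf("  %d patients, %d walk tests (%d app), %d patient-days\n",
              nrow(x$baseline), nrow(x$walktests),
              sum(x$walktests$source == "app"), nrow(x$daily)))
  if (!is.null(x$truth)) cat("  latent trajectory truth attached\n")
  invisible(x)
}

#' Export a cohort to CSV files
#'
#' Writes `baseline.csv`, `walktests.csv` and `daily.csv` (the schemas read
#' back by [load_dataset()]), plus `truth.csv` and a `config.yaml` snapshot
#' when the dataset carries them. Missing values are written as empty
#' fields; the dialect is comma-separated UTF-8 with a header row.
#'
#' @param dataset A `walk_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
export_cohort <- function(dataset, dir) {
  stopifnot(inherits(dataset, "walk_dataset"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", dir, call. = FALSE)
  }
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "")
    p
  }
  paths <- c(paths, wr(dataset$baseline, "baseline.csv"))
  paths <- c(paths, wr(dataset$walktests, "walktests.csv"))
  paths <- c(paths, wr(dataset$daily, "daily.csv"))
  if (!is.null(dataset$truth)) {
    paths <- c(paths, wr(dataset$truth, "truth.csv"))
  }
  if (!is.null(dataset$config)) {
    p <- file.path(dir, "config.yaml")
    yaml::write_yaml(unclass(dataset$config), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
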