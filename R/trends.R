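#' Adherence to the weekly self-test recommendation
#'
#' The program recommends one unsupervised 6MWT per week. Per-patient
#' adherence is the number of app-based tests divided by the recommended
#' count, capped at 100%; the overall value is the unweighted mean of the
#' per-patient fractions. Patients reaching the recommended count are
#' "fully adherent".
#'
#' @param walktests Walk-test data frame (columns `patient_id`, `source`).
#' @param recommended Recommended number of tests (default 12).
#' @return A list with `per_patient` (data frame of `patient_id`,
#'   `n_app_tests`, `adherence`), `overall`, `overall_sd`,
#'   `n_fully_adherent` and `fully_adherent_fraction`.
#' @export
compute_adherence <- function(walktests, recommended = 12) {
  if (!is.numeric(recommended) || length(recommended) != 1 || recommended <= 0) {
    stop("`recommended` must be a positive number", call. = FALSE)
  }
  patients <- unique(walktests$patient_id)
  app <- walktests[walktests$source == "app", , drop = FALSE]
  n_app <- table(factor(app$patient_id, levels = patients))
  per <- data.frame(
    patient_id = patients,
    n_app_tests = as.integer(n_app),
    stringsAsFactors = FALSE
  )
  per$adherence <- pmin(per$n_app_tests / recommended, 1)
  list(
    per_patient = per,
    overall = mean(per$adherence),
    overall_sd = stats::sd(per$adherence),
    n_fully_adherent = sum(per$n_app_tests >= recommended),
    fully_adherent_fraction = mean(per$n_app_tests >= recommended)
  )
}

#' Correlation with a normality-gated choice of method
#'
#' Computes the correlation between two paired vectors after listwise
#' deletion. By default the method is chosen by an Anderson-Darling
#' normality pretest on each margin at alpha = 0.05: Pearson when both
#' margins are compatible with normality, Spearman otherwise. With fewer
#' than 8 complete pairs the pretest is not defined and the rank-based
#' Spearman coefficient is used.
#'
#' @param x,y Paired numeric vectors.
#' @param method `"auto"` (the gate), or force `"pearson"` / `"spearman"`.
#' @param alpha Significance level of the normality pretest.
#' @return A list with `r`, `p`, `method` (the method actually used) and
#'   `n` (complete pairs).
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(50)
#' correlate(x, 2 * x + 1)$method   # "pearson", r = 1
correlate <- function(x, y, method = c("auto", "pearson", "spearman"),
                      alpha = 0.05) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance margin", call. = FALSE)
  }
  if (method == "auto") {
    method <- if (n >= 8 &&
                  nortest::ad.test(x)$p.value > alpha &&
                  nortest::ad.test(y)$p.value > alpha) {
      "pearson"
    } else {
      "spearman"
    }
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method,
                    exact = if (method == "spearman") FALSE else NULL)
  )
  list(r = unname(ct$estimate), p = ct$p.value, method = method, n = n)
}

#' Paired two-tailed Wilcoxon signed-rank test
#'
#' Compares paired pre/post measurements. Zero differences are dropped; the
#' null distribution of the rank sum is computed exactly (valid under ties)
#' when at most 25 non-zero differences remain, and by a normal
#' approximation with tie correction and continuity correction otherwise.
#'
#' @param pre,post Numeric vectors of equal length.
#' @return A list with `statistic` (V, the sum of the ranks of positive
#'   differences), `p.value` (two-tailed), `n` (non-zero pairs), `exact`,
#'   and the medians and IQRs of both samples.
#' @export
paired_wilcoxon <- function(pre, post) {
  if (length(pre) != length(post)) {
    stop("`pre` and `post` must have equal length", call. = FALSE)
  }
  ok <- stats::complete.cases(pre, post)
  pre <- pre[ok]
  post <- post[ok]
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero", call. = FALSE)
  if (n < 5) stop("need at least 5 non-zero differences", call. = FALSE)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  exact <- n <= 25
  if (exact) {
    # exact two-tailed p over all 2^n sign assignments, valid under ties:
    # convolve the distribution of the positive-rank sum on doubled ranks
    # (average ranks are multiples of 1/2, so 2r is integer)
    r2 <- as.integer(round(2 * r))
    counts <- 1
    for (ri in r2) {
      new <- c(counts, rep(0, ri))
      idx <- (ri + 1):(ri + length(counts))
      new[idx] <- new[idx] + counts
      counts <- new
    }
    v2 <- as.integer(round(2 * v))
    total <- 2^n
    p_le <- sum(counts[seq_len(v2 + 1)]) / total
    p_ge <- sum(counts[(v2 + 1):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    cc <- sign(v - mu) * 0.5
    z <- (v - mu - cc) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  qp <- qs(pre)
  qo <- qs(post)
  list(
    statistic = v, p.value = p, n = n, exact = exact,
    pre_median = qp[2], pre_iqr = c(qp[1], qp[3]),
    post_median = qo[2], post_iqr = c(qo[1], qo[3])
  )
}

# per-patient mean of a daily signal over one study week (floor convention)
week_signal_means <- function(daily, signal, week) {
  sub <- daily[daily$study_day %/% 7L == week & !is.na(daily[[signal]]), ,
               drop = FALSE]
  if (!nrow(sub)) return(stats::setNames(numeric(0), character(0)))
  tapply(sub[[signal]], sub$patient_id, mean)
}

#' Baseline vs. study-end comparison of mobility and pain measures
#'
#' One row per measure: the eight timed-up-and-go components (baseline test
#' vs. study-end test) and the daily pain score (week-0 vs. final-week
#' per-patient means), each compared with the two-tailed paired Wilcoxon
#' signed-rank test on pairwise-complete patients. No multiple-testing
#' correction is applied; the table's `note` attribute flags this.
#'
#' @param dataset A `walk_dataset` whose baseline table carries `tug1_*`
#'   and `tug_end_*` columns.
#' @return Data frame with measure, n, baseline and study-end
#'   medians/IQRs, and the Wilcoxon p value.
#' @export
prepost_report <- function(dataset) {
  b <- dataset$baseline
  n_weeks <- dataset_n_weeks(dataset)
  tug_parts <- c("stand_up", "walk_forward", "turnaround", "walk_back",
                 "sit_down", "total_walk_time", "mobility_time", "total_time")
  rows <- list()
  one <- function(measure, pre, post) {
    ok <- stats::complete.cases(pre, post)
    res <- tryCatch(paired_wilcoxon(pre[ok], post[ok]),
                    error = function(e) NULL)
    qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    qp <- qs(pre[ok])
    qo <- qs(post[ok])
    data.frame(
      measure = measure, n = sum(ok),
      pre_median = qp[2], pre_q1 = qp[1], pre_q3 = qp[3],
      post_median = qo[2], post_q1 = qo[1], post_q3 = qo[3],
      p_value = if (is.null(res)) NA_real_ else res$p.value,
      stringsAsFactors = FALSE
    )
  }
  for (part in tug_parts) {
    pre_col <- paste0("tug1_", part)
    post_col <- paste0("tug_end_", part)
    if (pre_col %in% names(b) && post_col %in% names(b)) {
      rows[[part]] <- one(paste0("tug_", part), b[[pre_col]], b[[post_col]])
    }
  }
  pain0 <- week_signal_means(dataset$daily, "pain", 0L)
  pain_end <- week_signal_means(dataset$daily, "pain", n_weeks)
  common <- intersect(names(pain0), names(pain_end))
  if (length(common) >= 5) {
    rows[["pain"]] <- one("pain_daily_mean",
                          as.numeric(pain0[common]),
                          as.numeric(pain_end[common]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "note") <- "p values are unadjusted for multiple testing"
  out
}

# same-day join of walk tests to daily records; a test at fractional study
# week x took place on day round(7 * x)
tests_with_daily <- function(dataset) {
  w <- dataset$walktests
  d <- dataset$daily
  w$study_day <- as.integer(round(7 * w$study_week))
  merge(w, d, by = c("patient_id", "study_day"))
}

#' Headline cross-signal correlations
#'
#' Reproduces the study-style correlation table on pooled observations:
#' same-day pain vs. steps and pain vs. 6MWT distance (days on which both
#' were submitted, pooled over patients without per-patient centring),
#' well-being vs. distance and vs. steps (always Spearman, the well-being
#' scale being a 3-level ordinal), and the patient-level baseline vs. end
#' and change vs. end distance correlations.
#'
#' @param dataset A `walk_dataset`.
#' @return Data frame with columns `pair`, `r`, `p`, `method`, `n`.
#' @export
crosscorr_report <- function(dataset) {
  d <- dataset$daily
  td <- tests_with_daily(dataset)
  b <- dataset$baseline

  safe_cor <- function(x, y, ...) {
    tryCatch(correlate(x, y, ...),
             error = function(e) list(r = NA_real_, p = NA_real_,
                                      method = NA_character_, n = sum(
                                        stats::complete.cases(x, y))))
  }
  rows <- list()
  add <- function(pair, res) {
    rows[[length(rows) + 1L]] <<- data.frame(
      pair = pair, r = res$r, p = res$p, method = res$method, n = res$n,
      stringsAsFactors = FALSE
    )
  }
  add("pain_vs_steps", safe_cor(d$pain, d$steps))
  add("pain_vs_distance", safe_cor(td$pain, td$distance_m))
  add("wellbeing_vs_distance",
      safe_cor(td$wellbeing, td$distance_m, method = "spearman"))
  add("wellbeing_vs_steps",
      safe_cor(d$wellbeing, d$steps, method = "spearman"))
  if (all(c("baseline_6mwt_m", "end_6mwt_m") %in% names(b))) {
    add("baseline_vs_end_distance",
        safe_cor(b$baseline_6mwt_m, b$end_6mwt_m))
    add("change_vs_end_distance",
        safe_cor(b$end_6mwt_m - b$baseline_6mwt_m, b$end_6mwt_m))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Distribution of daily well-being reports
#'
#' Counts and percentages of the 3-level well-being scale over all
#' submitted daily reports, pooled across patients.
#'
#' @param daily Daily-record data frame with a `wellbeing` column.
#' @return Data frame with `level` (bad/medium/good), `count` and
#'   `percent` (of all non-missing reports).
#' @export
wellbeing_distribution <- function(daily) {
  counts <- table(factor(daily$wellbeing, levels = 1:3))
  n <- sum(counts)
  data.frame(
    level = c("bad", "medium", "good"),
    count = as.integer(counts),
    percent = if (n > 0) 100 * as.integer(counts) / n else rep(NA_real_, 3),
    stringsAsFactors = FALSE
  )
}
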