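#!/usr/bin/env Rscript
# Step 2: descriptive statistics of the monitoring data.
#
# Adherence to the weekly self-test recommendation, the well-being
# distribution, the headline cross-signal correlations (normality-gated
# Pearson/Spearman), and the baseline-vs-study-end paired comparisons.

library(telewalk)

ds <- load_dataset("results/cohort")
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

adh <- compute_adherence(ds$walktests)
write.csv(adh$per_patient, "results/tables/adherence.csv", row.names = FALSE)
cat(sprintf("Adherence: overall %.2f%% (SD %.2f%%); %d of %d patients fully adherent (%.2f%%)\n",
            100 * adh$overall, 100 * adh$overall_sd, adh$n_fully_adherent,
            nrow(adh$per_patient), 100 * adh$fully_adherent_fraction))

wb <- wellbeing_distribution(ds$daily)
cat(sprintf("Well-being reports: %s\n",
            paste(sprintf("%s %.1f%%", wb$level, wb$percent), collapse = ", ")))

cc <- crosscorr_report(ds)
write.csv(cc, "results/tables/correlations.csv", row.names = FALSE)
cat("\nCross-signal correlations (pooled):\n")
print(cc, digits = 3)

pp <- prepost_report(ds)
write.csv(pp, "results/tables/prepost.csv", row.names = FALSE)
cat("\nBaseline vs study end (paired Wilcoxon;",
    attr(pp, "note"), "):\n")
print(pp, digits = 3)

# weekly trend series, normalised per patient for plotting
wk <- aggregate_weekly(ds)
dist_norm <- normalize_by_patient_mean(wk, "mean_distance_m")
pain_norm <- suppressWarnings(normalize_by_patient_mean(wk, "mean_pain"))
wk$dist_normalized <- dist_norm$normalized
wk$pain_centered <- pain_norm$normalized
write.csv(wk, "results/tables/weekly_series.csv", row.names = FALSE)
cat("\nwrote results/tables/{adherence,correlations,prepost,weekly_series}.csv\n")
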