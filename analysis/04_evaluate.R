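#!/usr/bin/env Rscript
# Step 4: leave-one-out evaluation tables.
#
# The RMSE-by-week table over all models (regression row: best subset of up
# to 4 features re-selected each week) and the baseline feature-count sweep
# from 1 to 8 features, with the pooled-grid selection (optimistic) and
# the honest within-fold selection side by side.

library(telewalk)

ds <- load_dataset("results/cohort")
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

sw <- sweep_weeks(ds)
write.csv(sw, "results/tables/rmse_by_week.csv", row.names = FALSE)
cat("LOO RMSE (m) by model and week:\n")
print(format_rmse_table(sw), row.names = FALSE)

# feature-count sweep at baseline over the in-clinic candidates
cand <- c("baseline_6mwt_m", "sex", "subj_gap_m", "tug_ratio",
          "age", "height_m", "weight_kg", "tug1_total_time")
fs <- feature_search(ds, 0, max_features = 8, candidates = cand)
write.csv(fs$per_k, "results/tables/feature_sweep.csv", row.names = FALSE)
cat("\nBest baseline feature subsets by size (pooled-grid selection):\n")
print(fs$per_k, digits = 4, row.names = FALSE)
cat(sprintf("overall best: %s (k = %d, RMSE %.2f m over %d subsets)\n",
            paste(fs$best$features, collapse = " + "), fs$best$k,
            fs$best$rmse, fs$n_subsets))
writeLines(fs$best$features, "results/tables/best_features.txt")

fh <- feature_search(ds, 0, max_features = 4, candidates = cand,
                     mode = "honest")
cat(sprintf("honest (within-fold selection) RMSE at baseline: %.2f m\n",
            fh$honest_rmse))
cat("wrote results/tables/{rmse_by_week,feature_sweep}.csv, best_features.txt\n")
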