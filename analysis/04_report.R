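#!/usr/bin/env Rscript
# Step 4 — report, plots and dashboard feed.
#
# Summarises the grid results, plots predicted-vs-actual occupancy for one
# ward over the last validation block, and exports the per-ward dashboard
# JSON feed for the final simulated day with a next-day forecast.

library(borcast)
library(data.table)

rep_dir <- "results/reports"
fig_dir <- "results/figures"
dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)

reports <- fread(file.path(rep_dir, "fold_reports.csv"))
preds <- fread(file.path(rep_dir, "predictions.csv"))
preds[, target_date := as.Date(target_date)]
ward_tab <- fread(file.path("results/data", "ward_daily.csv"))
ward_tab[, date := as.Date(date)]

summary <- fold_summary(reports)
best <- summary[fold == "Mean"][order(mae)][1]
cat(sprintf("Best model by mean cross-validated MAE: %s (MAE %.3f, RMSE %.3f, R2 %.3f)\n",
            best$model, best$mae, best$rmse, best$r2))

# two-month predicted-vs-actual view for the first ward, best ward model
ward_model <- summary[fold == "Mean"][grepl("^W", model)][order(mae)][1, model]
pw <- preds[model == ward_model]
ent <- sort(unique(pw$entity))[1]
last_fold <- max(pw$fold)
rng <- range(pw[fold == last_fold, target_date])
f <- file.path(fig_dir, sprintf("pred_vs_actual_%s_%s.png", ward_model, ent))
plot_predicted_vs_actual(pw[fold == last_fold], ent, rng[1], rng[2], file = f)
cat("Wrote", f, "\n")

# dashboard feed for the last day with a next-day prediction available
as_of <- max(pw$target_date) - 1
feed <- export_dashboard_feed(pw, ward_tab, as_of,
                              file = file.path(rep_dir, "dashboard_feed.json"))
cat(sprintf("Dashboard feed (%s): hospital %d/%d beds occupied (rate %.3f)\n",
            feed$as_of, feed$hospital$occupied, feed$hospital$capacity,
            feed$hospital$rate))
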