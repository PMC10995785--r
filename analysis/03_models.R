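#!/usr/bin/env Rscript
# Step 3 — hyperparameter search and the 12-model grid.
#
# Searches units x learning rate for the bidirectional 7-day ward model on
# fold 1 of the expanding cross-validation (the winning pair is reused across
# the grid), then runs all 12 model configurations through 5-fold expanding
# time-series cross-validation and writes the fold reports, the summary table
# and the per-model predictions under results/.
#
# Problem sizes are deliberately modest (a 30-room hospital, small unit
# counts, at most 15 epochs per fold) so the whole grid runs on a single
# laptop CPU core in well under an hour; see the methods vignette.

library(borcast)
library(data.table)

data_dir <- "results/data"
rep_dir <- "results/reports"
dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)

datasets <- readRDS(file.path(data_dir, "datasets.rds"))
split <- readRDS(file.path(data_dir, "split.rds"))
tc <- train_config(max_epochs = 15, batch_size = 256, patience = 4)

# samples for tuning: train+validation span of the ward 7-day variant
ws <- make_windows(datasets$ward, 7)
tv <- window_subset(ws, ws$target_date <= split$validation[2])
fold1 <- tscv_folds(tv, 5)[[1]]

space <- search_space(units = c(8, 16), learning_rates = c(1e-2, 3e-3))
tuned <- search_hyperparameters(
  model_spec("bilstm", 7, seed = 7), space, fold1$train, fold1$validation, tc)
cat("Hyperparameter search (fold 1, bilstm W7D):\n")
print(tuned$results[order(val_mae)])
cat(sprintf("Selected units = %d, learning rate = %g\n",
            tuned$best_spec$units, tuned$best_spec$learning_rate))
fwrite(tuned$results, file.path(rep_dir, "hyperparameter_search.csv"))

grid <- default_experiment_grid()
cat("\nRunning", nrow(grid), "models x 5 folds ...\n")
t0 <- Sys.time()
# cross-validate on the train+validation span only; the held-out test range
# is never shown to the fold machinery
res <- run_experiment_grid(
  grid, datasets, n_folds = 5, config = tc,
  spec_defaults = list(units = tuned$best_spec$units,
                       learning_rate = tuned$best_spec$learning_rate,
                       seed = 7),
  cv_end = split$validation[2]
)
cat("Grid finished in", format(Sys.time() - t0), "\n")

fwrite(res$reports, file.path(rep_dir, "fold_reports.csv"))
fwrite(res$summary, file.path(rep_dir, "fold_summary.csv"))
fwrite(res$predictions, file.path(rep_dir, "predictions.csv"))
jsonlite::write_json(
  split(res$reports, res$reports$model),
  file.path(rep_dir, "experiment.json"), auto_unbox = TRUE, digits = NA
)

cat("\nPer-model cross-validated means:\n")
print(res$summary[fold == "Mean"][order(mae)])
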