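# Experiment orchestration: hyperparameter search over units x learning rate,
# expanding 5-fold time-series cross-validation, and the full 12-model grid
# (lstm/bilstm x W7D/W30D/R3D/R7D/RS3D/RS7D).

#' Hyperparameter search space
#'
#' @param units Candidate recurrent unit counts (nonempty).
#' @param learning_rates Candidate Adam learning rates (nonempty, > 0).
#' @param budget Maximum number of (units, lr) combinations to evaluate; a
#'   budget at least as large as the grid evaluates every combination exactly
#'   once, a smaller budget evaluates a seeded random subset.
#' @param seed Seed for the subset draw.
#' @return A `search_space` list.
#' @export
search_space <- function(units = c(16L, 32L, 64L, 128L),
                         learning_rates = c(1e-2, 1e-3, 1e-4),
                         budget = Inf, seed = 1L) {
  if (length(units) < 1 || length(learning_rates) < 1)
    stop("candidate sets must be nonempty", call. = FALSE)
  if (any(learning_rates <= 0)) stop("learning rates must be > 0", call. = FALSE)
  if (budget < 1) stop("budget must be >= 1", call. = FALSE)
  structure(list(units = sort(unique(as.integer(units))),
                 learning_rates = sort(unique(learning_rates)),
                 budget = budget, seed = as.integer(seed)),
            class = "search_space")
}

#' Search units and learning rate on a train/validation pair
#'
#' Trains one model per candidate (units, learning rate) combination and
#' returns the specification with the lowest validation MAE. Ties break
#' toward smaller units, then smaller learning rate. Candidates whose
#' training diverges (non-finite loss) are recorded as failed; if every
#' candidate fails, an error lists them.
#'
#' @param spec Template [model_spec()]; `units` and `learning_rate` are
#'   overridden per candidate.
#' @param space A [search_space()].
#' @param train,validation `window_set`s.
#' @param config A [train_config()].
#' @return List with `best_spec` (a `model_spec`) and `results` (a
#'   `data.table` of candidates and their validation MAE).
#' @export
search_hyperparameters <- function(spec, space, train, validation,
                                   config = train_config()) {
  stopifnot(inherits(spec, "model_spec"), inherits(space, "search_space"))
  cand <- data.table::CJ(units = space$units, lr = space$learning_rates)
  data.table::setorder(cand, units, lr)
  if (space$budget < nrow(cand)) {
    keep <- with_seed(space$seed, sort(sample.int(nrow(cand), space$budget)))
    cand <- cand[keep]
  }
  cand[, val_mae := NA_real_]
  for (i in seq_len(nrow(cand))) {
    sp <- spec
    sp$units <- cand$units[i]
    sp$learning_rate <- cand$lr[i]
    m <- tryCatch({
      mdl <- if (sp$use_static)
        build_fusion_forecaster(sp, dim(train$X)[3], ncol(train$S))
      else
        build_base_forecaster(sp, dim(train$X)[3])
      mdl <- train_forecaster(mdl, train, validation, config)
      mean(abs(predict(mdl, validation) - validation$y))
    }, error = function(e) NA_real_)
    cand[i, val_mae := m]
  }
  if (all(is.na(cand$val_mae)))
    stop("every candidate diverged: ",
         paste(sprintf("(units=%d, lr=%g)", cand$units, cand$lr), collapse = ", "),
         call. = FALSE)
  ok <- cand[!is.na(val_mae)]
  data.table::setorder(ok, val_mae, units, lr)
  best <- spec
  best$units <- ok$units[1]
  best$learning_rate <- ok$lr[1]
  list(best_spec = best, results = cand[])
}

#' The study's default experiment grid
#'
#' Twelve model configurations: architectures lstm and bilstm crossed with
#' W7D, W30D (ward level, windows 7/30, no static branch), R3D, R7D (room
#' level, windows 3/7), RS3D, RS7D (room level, windows 3/7, static fusion).
#'
#' @return `data.table` with columns `model`, `architecture`, `config`,
#'   `level`, `variant`, `window_len`, `use_static` — 12 distinct rows.
#' @export
default_experiment_grid <- function() {
  conf <- data.table::data.table(
    config = c("W7D", "W30D", "R3D", "R7D", "RS3D", "RS7D"),
    level = c("ward", "ward", "room", "room", "room", "room"),
    variant = c("ward", "ward", "room", "room", "room_static", "room_static"),
    window_len = c(7L, 30L, 3L, 7L, 3L, 7L),
    use_static = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  )
  grid <- data.table::CJ(architecture = c("lstm", "bilstm"), config = conf$config,
                         sorted = FALSE)
  grid <- conf[grid, on = "config"]
  grid[, model := paste0(config, "_", architecture)]
  data.table::setcolorder(grid, c("model", "architecture", "config", "level",
                                  "variant", "window_len", "use_static"))
  grid[]
}

build_for <- function(spec, ws) {
  if (spec$use_static) build_fusion_forecaster(spec, dim(ws$X)[3], ncol(ws$S))
  else build_base_forecaster(spec, dim(ws$X)[3])
}

#' Run expanding time-series cross-validation for one model spec
#'
#' Builds the folds with [tscv_folds()], trains a fresh model per fold on the
#' fold's (expanding) training blocks with early stopping against the fold's
#' validation block, and evaluates MAE/MSE/RMSE/R-squared on that validation
#' block. Fold k's model is seeded `spec$seed + 1000 * k`, so the whole run is
#' deterministic.
#'
#' @param spec A [model_spec()].
#' @param ws A `window_set` (its windows should be built with
#'   `spec$window_len`).
#' @param n_folds Number of folds (default 5).
#' @param config A [train_config()].
#' @param model_id Label used in the report rows (defaults to a spec-derived
#'   id).
#' @return List with `reports` (`data.table`: model, fold, mae, mse, rmse, r2,
#'   n) and `predictions` (`data.table`: model, fold, entity, target_date,
#'   y_true, y_pred).
#' @export
run_tscv <- function(spec, ws, n_folds = 5L, config = train_config(),
                     model_id = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(ws, "window_set"))
  model_id <- model_id %||%
    sprintf("%s_w%d%s", spec$architecture, spec$window_len,
            if (spec$use_static) "_static" else "")
  folds <- tscv_folds(ws, n_folds)
  reports <- vector("list", length(folds))
  preds <- vector("list", length(folds))
  for (f in folds) {
    sp <- spec
    sp$seed <- spec$seed + 1000L * f$fold
    mdl <- build_for(sp, f$train)
    mdl <- tryCatch(
      train_forecaster(mdl, f$train, f$validation, config),
      error = function(e) stop("fold ", f$fold, ": ", conditionMessage(e),
                               call. = FALSE)
    )
    yhat <- predict(mdl, f$validation)
    m <- compute_metrics(f$validation$y, yhat)
    reports[[f$fold]] <- data.table::data.table(
      model = model_id, fold = f$fold, mae = m$mae, mse = m$mse,
      rmse = m$rmse, r2 = m$r2, n = m$n
    )
    preds[[f$fold]] <- data.table::data.table(
      model = model_id, fold = f$fold, entity = f$validation$entity,
      target_date = f$validation$target_date,
      y_true = f$validation$y, y_pred = yhat
    )
  }
  list(reports = data.table::rbindlist(reports),
       predictions = data.table::rbindlist(preds))
}

#' Run the full experiment grid
#'
#' Executes [run_tscv()] for every row of the grid against the matching
#' dataset variant, reusing windowed samples across rows that share a variant
#' and window length.
#'
#' @param grid A grid from [default_experiment_grid()] (or a subset / an
#'   edited copy with the same columns).
#' @param datasets Named list of `model_dataset`s keyed by variant:
#'   `ward`, `room`, and (for RS rows) `room_static`.
#' @param n_folds Folds per model.
#' @param config A [train_config()].
#' @param spec_defaults Named list of [model_spec()] arguments applied to
#'   every row (e.g. `units`, `learning_rate`, `seed`).
#' @param cv_end Optional last target date admitted into the folds; samples
#'   beyond it (typically a held-out test range) are excluded from
#'   cross-validation.
#' @return List with `reports` (all fold rows), `summary`
#'   ([fold_summary()] of the reports) and `predictions`.
#' @export
run_experiment_grid <- function(grid, datasets, n_folds = 5L,
                                config = train_config(),
                                spec_defaults = list(), cv_end = NULL) {
  grid <- data.table::as.data.table(grid)
  need <- unique(grid$variant)
  missing <- setdiff(need, names(datasets))
  if (length(missing))
    stop("datasets list is missing variant(s): ",
         paste(missing, collapse = ", "),
         if ("room_static" %in% missing)
           " (static fusion configurations need a 'room_static' dataset)",
         call. = FALSE)
  win_cache <- new.env(parent = emptyenv())
  all_rep <- list(); all_pred <- list()
  for (i in seq_len(grid[, .N])) {
    row <- grid[i]
    key <- paste(row$variant, row$window_len, sep = "_")
    if (is.null(win_cache[[key]])) {
      w <- make_windows(datasets[[row$variant]], row$window_len)
      if (!is.null(cv_end))
        w <- window_subset(w, w$target_date <= as.Date(cv_end))
      win_cache[[key]] <- w
    }
    ws <- win_cache[[key]]
    spec <- do.call(model_spec, c(
      list(architecture = row$architecture, window_len = row$window_len,
           use_static = row$use_static),
      spec_defaults
    ))
    res <- run_tscv(spec, ws, n_folds, config, model_id = row$model)
    all_rep[[i]] <- res$reports
    all_pred[[i]] <- res$predictions
  }
  reports <- data.table::rbindlist(all_rep)
  list(reports = reports, summary = fold_summary(reports),
       predictions = data.table::rbindlist(all_pred))
}
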