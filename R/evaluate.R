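# Evaluation and reporting: the four forecast metrics, fold summaries with a
# mean row at 3-decimal precision, split proportions, predicted-vs-actual
# plots, and the dashboard data feed.

#' Forecast error metrics
#'
#' Computes MAE = mean |y - yhat|, MSE = mean (y - yhat)^2, RMSE = sqrt(MSE),
#' and R^2 = 1 - SSR/SST where SSR = sum (y - yhat)^2 and SST is the total sum
#' of squares around the mean of `y_true`. R^2 can be negative (worse than
#' predicting the mean) and is undefined for constant targets (returned as
#' `NA` with a warning).
#'
#' @param y_true,y_pred Equal-length nonempty numeric vectors.
#' @return A `metrics_record`: list with `mae`, `mse`, `rmse`, `r2`, `n`.
#' @examples
#' compute_metrics(c(0.2, 0.4, 0.6), c(0.3, 0.5, 0.5))
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length (", length(y_true),
         " vs ", length(y_pred), ")", call. = FALSE)
  if (length(y_true) == 0) stop("empty prediction set", call. = FALSE)
  err <- y_true - y_pred
  mae <- mean(abs(err))
  mse <- mean(err^2)
  ssr <- sum(err^2)
  sst <- sum((y_true - mean(y_true))^2)
  r2 <- if (sst == 0) {
    warning("constant targets: R^2 is undefined (SST = 0)")
    NA_real_
  } else 1 - ssr / sst
  structure(list(mae = mae, mse = mse, rmse = sqrt(mse), r2 = r2,
                 n = length(y_true)),
            class = "metrics_record")
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf("<metrics_record> n=%d MAE=%.4f MSE=%.4f RMSE=%.4f R2=%s\n",
              x$n, x$mae, x$mse, x$rmse,
              if (is.na(x$r2)) "NA" else sprintf("%.4f", x$r2)))
  invisible(x)
}

#' Per-model fold summary with mean rows
#'
#' Arranges fold reports into the study's reporting shape: one row per fold
#' per model plus a `"Mean"` row holding the arithmetic mean of the fold
#' values, every cell rounded half-up to 3 decimals.
#'
#' @param reports Data frame with columns `model`, `fold`, `mae`, `mse`,
#'   `rmse`, `r2` (one row per model-fold); every model must have the same
#'   number of folds.
#' @return `data.table` with columns `model`, `fold` (fold numbers as
#'   character, then `"Mean"`), `mae`, `mse`, `rmse`, `r2`.
#' @export
fold_summary <- function(reports) {
  rep_ <- data.table::as.data.table(reports)
  need <- c("model", "fold", "mae", "mse", "rmse", "r2")
  if (!all(need %in% names(rep_)))
    stop("reports must have columns ", paste(need, collapse = ", "), call. = FALSE)
  counts <- rep_[, .N, by = model]
  if (length(unique(counts$N)) != 1)
    stop("ragged fold counts across models: ",
         paste(sprintf("%s=%d", counts$model, counts$N), collapse = ", "),
         call. = FALSE)
  metric_cols <- c("mae", "mse", "rmse", "r2")
  out <- lapply(unique(rep_$model), function(m) {
    d <- rep_[model == m][order(fold)]
    folds <- d[, c(list(fold = as.character(fold)),
                   lapply(.SD, function(x) round_half_up(x, 3))),
               .SDcols = metric_cols]
    mean_row <- d[, c(list(fold = "Mean"),
                      lapply(.SD, function(x) round_half_up(mean(x), 3))),
                  .SDcols = metric_cols]
    cbind(model = m, rbind(folds, mean_row))
  })
  data.table::rbindlist(out)[]
}

#' Partition proportions as printed percentages
#'
#' @param counts Nonnegative integer row counts (total > 0).
#' @return Percentages (`100 * count / total`), rounded half-up to 1 decimal.
#' @examples
#' split_proportions(c(3, 1))  # 75.0 25.0
#' @export
split_proportions <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("total count is zero", call. = FALSE)
  round_half_up(100 * counts / total, 1)
}

#' Plot predicted vs actual occupancy rates for one entity
#'
#' Two aligned daily curves (actual and predicted rate) over a date range,
#' with the rate axis clamped to `[0, 1]`.
#'
#' @param predictions Data frame with columns `entity`, `target_date`,
#'   `y_true`, `y_pred` (as exported by [run_tscv()]).
#' @param entity Entity identifier to plot.
#' @param from,to Date range (inclusive).
#' @param file Optional output file; written with [ggplot2::ggsave()].
#' @return The ggplot object.
#' @export
plot_predicted_vs_actual <- function(predictions, entity, from, to, file = NULL) {
  pr <- data.table::as.data.table(predictions)
  if (!entity %in% pr$entity)
    stop("entity '", entity, "' not found; available: ",
         paste(utils::head(sort(unique(pr$entity)), 20), collapse = ", "),
         call. = FALSE)
  from <- as.Date(from); to <- as.Date(to)
  sel <- pr$entity == entity & pr$target_date >= from & pr$target_date <= to
  d <- pr[sel]
  if (nrow(d) == 0)
    stop("no predictions for '", entity, "' between ", from, " and ", to,
         call. = FALSE)
  long <- data.table::melt(
    d[, .(target_date, Actual = y_true, Predicted = y_pred)],
    id.vars = "target_date", variable.name = "series", value.name = "rate"
  )
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = target_date, y = rate, colour = series)) +
    ggplot2::geom_line(linewidth = 0.5) +
    ggplot2::scale_colour_manual(values = c(Actual = "#2166ac", Predicted = "#b2182b")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Bed occupancy rate", colour = NULL,
                  title = paste("Occupancy:", entity)) +
    ggplot2::theme_minimal()
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 8, height = 3.5, dpi = 150)
  p
}

#' Export the dashboard data feed
#'
#' Builds the per-ward JSON feed a bed-management dashboard consumes: for an
#' as-of date, each ward's capacity, occupied and free beds, occupancy rate,
#' and the next-day predicted rate, plus the hospital-level aggregate
#' (occupied / capacity over all wards).
#'
#' @param predictions Prediction table (`entity`, `target_date`, `y_pred`,
#'   ...); predictions with `target_date == as_of + 1` supply the next-day
#'   forecast (`NA` where absent).
#' @param table Ward-level daily occupancy table.
#' @param as_of As-of date; must be present in `table`.
#' @param file Optional path; the document is written as JSON.
#' @return The feed as a list (invisibly when `file` is given).
#' @export
export_dashboard_feed <- function(predictions, table, as_of, file = NULL) {
  tab <- data.table::as.data.table(table)
  as_of <- as.Date(as_of)
  if ("level" %in% names(tab)) tab <- tab[level == "ward"]
  day <- tab[date == as_of]
  if (nrow(day) == 0)
    stop("as-of date ", as_of, " is not covered by the occupancy table",
         call. = FALSE)
  pr <- data.table::as.data.table(predictions)
  nxt <- pr[target_date == as_of + 1]
  wards <- lapply(seq_len(nrow(day)), function(i) {
    w <- day[i]
    p <- nxt[entity == w$entity]
    list(ward = w$entity, capacity = w$capacity, occupied = w$occupied,
         free = w$capacity - w$occupied, rate = w$rate,
         predicted_rate_next_day = if (nrow(p)) p$y_pred[1] else NA_real_)
  })
  doc <- list(
    as_of = as.character(as_of),
    hospital = list(capacity = sum(day$capacity), occupied = sum(day$occupied),
                    free = sum(day$capacity) - sum(day$occupied),
                    rate = sum(day$occupied) / sum(day$capacity)),
    wards = wards
  )
  if (!is.null(file)) {
    jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA, null = "null")
    return(invisible(doc))
  }
  doc
}

#' Read a dashboard feed written by [export_dashboard_feed()]
#' @param file JSON file path.
#' @return The feed list.
#' @export
read_dashboard_feed <- function(file) {
  jsonlite::read_json(file, simplifyVector = FALSE)
}
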