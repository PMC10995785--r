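# Sliding-window supervised samples, chronological train/validation/test
# splits, and expanding 5-fold time-series cross-validation. Partition
# membership is decided by the target date only: a window may read features
# from earlier partitions, since past data are legitimately observable at
# prediction time.

#' Build sliding-window samples from a model dataset
#'
#' For every entity, consecutive-date windows of length `window_len` (stride
#' 1) predict the occupancy rate `horizon` days after the window. No window
#' spans two entities. An entity with fewer than `window_len + horizon`
#' observed days contributes zero samples (logged, not an error).
#'
#' @param dataset A `model_dataset` from [encode_and_normalize()].
#' @param window_len Window length in days (>= 1); the study uses 3, 7 and 30.
#' @param horizon Forecast horizon in days (default 1 = next day).
#' @return A `window_set`: list with `X` (samples x window_len x dynamic
#'   features array), `S` (samples x 14 static matrix, or `NULL`), `y` (target
#'   rates), `entity`, `target_date`, plus feature bookkeeping. Samples are
#'   ordered by entity then target date.
#' @export
make_windows <- function(dataset, window_len, horizon = 1L) {
  stopifnot(inherits(dataset, "model_dataset"))
  window_len <- as.integer(window_len); horizon <- as.integer(horizon)
  if (window_len < 1 || horizon < 1)
    stop("window_len and horizon must be >= 1", call. = FALSE)
  d <- dataset$data
  dyn <- as.matrix(d[, dataset$dynamic_cols, with = FALSE])
  ent <- d$entity
  dates <- d$date

  starts <- integer(0); ent_out <- character(0)
  for (e in unique(ent)) {
    idx <- which(ent == e)
    if (any(diff(as.integer(dates[idx])) != 1L))
      stop("dates are not contiguous for entity ", e, call. = FALSE)
    n_e <- length(idx) - window_len - horizon + 1L
    if (n_e < 1L) {
      message("entity ", e, " has too few days (", length(idx),
              ") for window ", window_len, " + horizon ", horizon,
              "; contributing no samples")
      next
    }
    starts <- c(starts, idx[seq_len(n_e)])
    ent_out <- c(ent_out, rep(e, n_e))
  }
  n <- length(starts)
  Fd <- ncol(dyn)
  X <- array(0, dim = c(n, window_len, Fd),
             dimnames = list(NULL, NULL, dataset$dynamic_cols))
  for (k in seq_len(window_len)) X[, k, ] <- dyn[starts + k - 1L, , drop = FALSE]
  tgt <- starts + window_len + horizon - 1L
  y <- d$rate[tgt]
  target_date <- dates[tgt]

  S <- NULL
  if (!is.null(dataset$static_cols)) {
    stat <- as.matrix(d[starts, dataset$static_cols, with = FALSE])
    S <- stat
    colnames(S) <- dataset$static_cols
  }
  structure(
    list(X = X, S = S, y = y, entity = ent_out, target_date = target_date,
         dynamic_cols = dataset$dynamic_cols, static_cols = dataset$static_cols,
         rate_col = match("rate", dataset$dynamic_cols),
         window_len = window_len, horizon = horizon),
    class = "window_set"
  )
}

#' Number of samples in a window set
#' @param ws A `window_set`.
#' @return Integer sample count.
#' @export
n_samples <- function(ws) length(ws$y)

#' Subset a window set by sample index
#' @param ws A `window_set`.
#' @param idx Integer or logical index.
#' @return A `window_set` with the selected samples, order preserved.
#' @export
window_subset <- function(ws, idx) {
  out <- ws
  out$X <- ws$X[idx, , , drop = FALSE]
  if (!is.null(ws$S)) out$S <- ws$S[idx, , drop = FALSE]
  out$y <- ws$y[idx]
  out$entity <- ws$entity[idx]
  out$target_date <- ws$target_date[idx]
  out
}

#' @export
print.window_set <- function(x, ...) {
  cat("<window_set> ", n_samples(x), " samples, window ", x$window_len,
      " x ", length(x$dynamic_cols), " dynamic features",
      if (!is.null(x$S)) paste0(" + ", ncol(x$S), " static"), "\n", sep = "")
  invisible(x)
}

#' Chronological split specification
#'
#' Three ordered, non-overlapping date ranges. The study splits at
#' 2020-05-27..2021-12-31 (train), 2022-01-01..2022-06-30 (validation),
#' 2022-07-01..2022-11-21 (test).
#'
#' @param train,validation,test Length-2 date vectors `(start, end)`.
#' @return A `split_spec` list.
#' @export
split_spec <- function(train, validation, test) {
  rng <- function(x) {
    x <- as.Date(x)
    if (length(x) != 2 || x[1] > x[2]) stop("each range needs start <= end", call. = FALSE)
    x
  }
  train <- rng(train); validation <- rng(validation); test <- rng(test)
  if (!(train[2] < validation[1] && validation[2] < test[1]))
    stop("ranges must be ordered: train < validation < test", call. = FALSE)
  structure(list(train = train, validation = validation, test = test),
            class = "split_spec")
}

#' Split windowed samples chronologically by target date
#'
#' A sample belongs to the partition whose date range contains its *target*
#' date; its input window may reach back into an earlier partition. Samples
#' whose target date falls in none of the ranges are dropped with a warning.
#'
#' @param ws A `window_set`.
#' @param spec A [split_spec()].
#' @return Named list of `window_set`s: `train`, `validation`, `test`.
#' @export
chronological_split <- function(ws, spec) {
  stopifnot(inherits(ws, "window_set"), inherits(spec, "split_spec"))
  member <- function(rng) ws$target_date >= rng[1] & ws$target_date <= rng[2]
  parts <- lapply(spec[c("train", "validation", "test")],
                  function(rng) window_subset(ws, member(rng)))
  dropped <- n_samples(ws) - sum(vapply(parts, n_samples, integer(1)))
  if (dropped > 0)
    warning(dropped, " sample(s) fall outside every partition and were dropped")
  empty <- names(parts)[vapply(parts, n_samples, integer(1)) == 0]
  if (length(empty))
    warning("empty partition(s): ", paste(empty, collapse = ", "))
  parts
}

#' Expanding time-series cross-validation folds
#'
#' Cuts the span of target dates into `n_folds + 1` equal contiguous blocks
#' (earlier blocks take any remainder day). Fold k trains on blocks 1..k and
#' validates on block k + 1, so training ranges are nested and every fold is
#' leakage-free.
#'
#' @param ws A `window_set`.
#' @param n_folds Number of folds (>= 2; the study uses 5).
#' @return List of folds, each with `fold`, `train_range`, `validation_range`,
#'   and `train` / `validation` window sets.
#' @export
tscv_folds <- function(ws, n_folds = 5L) {
  stopifnot(inherits(ws, "window_set"))
  n_folds <- as.integer(n_folds)
  if (n_folds < 2) stop("n_folds must be >= 2", call. = FALSE)
  days <- seq(min(ws$target_date), max(ws$target_date), by = "day")
  nb <- n_folds + 1L
  if (length(days) < nb)
    stop("date span of ", length(days), " day(s) too short for ", nb,
         " blocks", call. = FALSE)
  base <- length(days) %/% nb
  rem <- length(days) %% nb
  sizes <- rep(base, nb) + c(rep(1L, rem), rep(0L, nb - rem))
  ends <- cumsum(sizes)
  block_start <- days[c(1L, ends[-nb] + 1L)]
  block_end <- days[ends]

  lapply(seq_len(n_folds), function(k) {
    tr <- c(block_start[1], block_end[k])
    va <- c(block_start[k + 1], block_end[k + 1])
    list(
      fold = k,
      train_range = tr,
      validation_range = va,
      train = window_subset(ws, ws$target_date >= tr[1] & ws$target_date <= tr[2]),
      validation = window_subset(ws, ws$target_date >= va[1] & ws$target_date <= va[2])
    )
  })
}
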