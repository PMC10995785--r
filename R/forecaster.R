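# Forecaster API: model specifications, construction of the base and fusion
# architectures, the training loop (MSE loss, Adam, early stopping on
# validation MAE), prediction, checkpointing, and naive baselines.

#' Model specification for an occupancy forecaster
#'
#' Describes one model configuration. The study's twelve models are the cross
#' of `architecture` in (lstm, bilstm) with the six configurations W7D, W30D
#' (ward level, windows 7/30), R3D, R7D (room level, windows 3/7) and RS3D,
#' RS7D (room level with static fusion, windows 3/7).
#'
#' @param architecture `"lstm"` (unidirectional) or `"bilstm"` (bidirectional,
#'   concatenated directions, so the hidden dimension doubles).
#' @param window_len Input window length in days (the study uses 3, 7, 30).
#' @param units Recurrent units per layer and direction.
#' @param learning_rate Adam learning rate (> 0).
#' @param use_static Whether the model fuses the 14 static room variables.
#' @param dropout Dropout rate for the two static-branch dense layers,
#'   in `[0, 1)`.
#' @param static_widths Widths of the two static-branch dense layers.
#' @param leaky_slope LeakyReLU negative slope (> 0).
#' @param seed Seed for weight initialisation and training randomness.
#' @return A `model_spec` list.
#' @export
model_spec <- function(architecture = c("bilstm", "lstm"), window_len = 7L,
                       units = 32L, learning_rate = 1e-3, use_static = FALSE,
                       dropout = 0.3, static_widths = c(64L, 32L),
                       leaky_slope = 0.01, seed = 1L) {
  architecture <- match.arg(architecture)
  if (window_len < 1) stop("window_len must be >= 1", call. = FALSE)
  if (units < 1) stop("units must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)", call. = FALSE)
  if (length(static_widths) != 2 || any(static_widths < 1))
    stop("static_widths must be two positive integers", call. = FALSE)
  if (leaky_slope <= 0) stop("leaky_slope must be > 0", call. = FALSE)
  structure(
    list(architecture = architecture, window_len = as.integer(window_len),
         units = as.integer(units), learning_rate = learning_rate,
         use_static = isTRUE(use_static), dropout = dropout,
         static_widths = as.integer(static_widths),
         leaky_slope = leaky_slope, seed = as.integer(seed)),
    class = "model_spec"
  )
}

#' Training configuration
#'
#' The compile choices follow the study (MSE loss, Adam optimizer, MAE as the
#' monitored metric); epoch/batch/patience values are this package's declared
#' defaults since none are reported.
#'
#' @param max_epochs Maximum training epochs.
#' @param batch_size Minibatch size (>= 1).
#' @param patience Early-stopping patience on validation MAE (must be smaller
#'   than `max_epochs`); the best-validation weights are restored.
#' @param shuffle Whether to shuffle training samples each epoch.
#' @return A `train_config` list.
#' @export
train_config <- function(max_epochs = 200L, batch_size = 256L, patience = 10L,
                         shuffle = TRUE) {
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  if (patience >= max_epochs)
    stop("patience must be smaller than max_epochs", call. = FALSE)
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), shuffle = isTRUE(shuffle)),
            class = "train_config")
}

hidden_dim <- function(spec) {
  spec$units * if (spec$architecture == "bilstm") 2L else 1L
}

#' Build the base recurrent forecaster
#'
#' Layer stack: recurrent (sequences out) -> LeakyReLU -> recurrent
#' (sequences out) -> LeakyReLU -> attention-with-context -> LeakyReLU ->
#' dense(1) -> sigmoid, so every prediction lies strictly in (0, 1).
#' Bidirectional variants concatenate the two directions (hidden dimension
#' `2 * units`).
#'
#' @param spec A [model_spec()] with `use_static = FALSE`.
#' @param n_features Number of dynamic input features per timestep.
#' @return A `bor_forecaster`.
#' @export
build_base_forecaster <- function(spec, n_features) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$use_static)
    stop("spec has use_static = TRUE; use build_fusion_forecaster()", call. = FALSE)
  if (n_features < 1) stop("n_features must be >= 1", call. = FALSE)
  bi <- spec$architecture == "bilstm"
  d <- hidden_dim(spec)
  params <- with_seed(spec$seed, list(
    l1 = rec_init(n_features, spec$units, bi),
    l2 = rec_init(d, spec$units, bi),
    att = attn_init(d),
    head = dense_init(d, 1L)
  ))
  structure(list(spec = spec, params = params, fusion = FALSE,
                 n_dynamic = as.integer(n_features), n_static = 0L,
                 trained = FALSE, history = NULL),
            class = "bor_forecaster")
}

#' Build the static+dynamic fusion forecaster
#'
#' The dynamic branch is the base stack up to and including the
#' post-attention activation; the static branch passes the static vector
#' through two dense + LeakyReLU + dropout blocks; the two branch outputs are
#' concatenated into a single dense(1) + sigmoid head.
#'
#' @param spec A [model_spec()] with `use_static = TRUE`.
#' @param n_dynamic Number of dynamic features per timestep.
#' @param n_static Number of static features (default 14: room grade code plus
#'   13 flags).
#' @return A `bor_forecaster`.
#' @export
build_fusion_forecaster <- function(spec, n_dynamic, n_static = 14L) {
  stopifnot(inherits(spec, "model_spec"))
  if (!spec$use_static)
    stop("spec has use_static = FALSE; use build_base_forecaster()", call. = FALSE)
  if (n_static < 1) stop("n_static must be >= 1", call. = FALSE)
  bi <- spec$architecture == "bilstm"
  d <- hidden_dim(spec)
  w <- spec$static_widths
  params <- with_seed(spec$seed, list(
    l1 = rec_init(n_dynamic, spec$units, bi),
    l2 = rec_init(d, spec$units, bi),
    att = attn_init(d),
    s1 = dense_init(n_static, w[1]),
    s2 = dense_init(w[1], w[2]),
    head = dense_init(d + w[2], 1L)
  ))
  structure(list(spec = spec, params = params, fusion = TRUE,
                 n_dynamic = as.integer(n_dynamic),
                 n_static = as.integer(n_static),
                 trained = FALSE, history = NULL),
            class = "bor_forecaster")
}

#' Number of trainable parameters of a forecaster
#' @param model A `bor_forecaster`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "bor_forecaster"))
  as.integer(tree_count(model$params))
}

#' @export
print.bor_forecaster <- function(x, ...) {
  cat("<bor_forecaster> ", x$spec$architecture,
      if (x$fusion) " + static fusion", ", window ", x$spec$window_len,
      ", units ", x$spec$units, ", ", n_params(x), " parameters",
      if (x$trained) " (trained)", "\n", sep = "")
  invisible(x)
}

check_dims <- function(model, ws) {
  if (dim(ws$X)[3] != model$n_dynamic)
    stop("sample set has ", dim(ws$X)[3], " dynamic features but the model expects ",
         model$n_dynamic, call. = FALSE)
  if (model$fusion) {
    if (is.null(ws$S))
      stop("fusion model requires samples with a static matrix", call. = FALSE)
    if (ncol(ws$S) != model$n_static)
      stop("sample set has ", ncol(ws$S), " static features but the model expects ",
           model$n_static, call. = FALSE)
  }
}

eval_mae_loss <- function(model, ws, batch_size = 1024L) {
  p <- predict(model, ws, batch_size = batch_size)
  c(loss = mean((p - ws$y)^2), mae = mean(abs(p - ws$y)))
}

#' Train a forecaster
#'
#' Minibatch training with MSE loss and the Adam optimizer at the spec's
#' learning rate, monitoring MAE. With a validation set, early stopping
#' restores the weights with the best validation MAE after `patience` epochs
#' without improvement. Fully deterministic given the spec seed.
#'
#' @param model A `bor_forecaster`.
#' @param train Training `window_set` (nonempty).
#' @param validation Optional validation `window_set`; enables early stopping.
#' @param config A [train_config()].
#' @return The trained model, with a `history` data.frame (`epoch`, `loss`,
#'   `mae`, and `val_loss`/`val_mae` when validating) attached.
#' @export
train_forecaster <- function(model, train, validation = NULL,
                             config = train_config()) {
  stopifnot(inherits(model, "bor_forecaster"), inherits(train, "window_set"),
            inherits(config, "train_config"))
  if (n_samples(train) == 0) stop("training set is empty", call. = FALSE)
  check_dims(model, train)
  if (!is.null(validation) && n_samples(validation) > 0) check_dims(model, validation)
  else validation <- NULL

  spec <- model$spec
  n <- n_samples(train)
  state <- adam_init(model$params)
  use_dropout <- model$fusion && spec$dropout > 0
  w <- spec$static_widths

  hist <- vector("list", config$max_epochs)
  best <- list(metric = Inf, params = model$params, wait = 0L)

  with_seed(spec$seed + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      idx <- if (config$shuffle) sample.int(n) else seq_len(n)
      ep_loss <- 0; ep_mae <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        bi <- idx[start:min(start + config$batch_size - 1L, n)]
        Xl <- x_to_list(train$X, bi)
        S <- if (model$fusion) train$S[bi, , drop = FALSE] else NULL
        masks <- if (use_dropout) list(
          dropout_mask(length(bi), w[1], spec$dropout),
          dropout_mask(length(bi), w[2], spec$dropout)
        ) else NULL
        fw <- model_fwd(model, Xl, S, masks)
        err <- fw$pred - train$y[bi]
        loss <- mean(err^2)
        if (!is.finite(loss))
          stop("non-finite training loss at epoch ", epoch, call. = FALSE)
        grads <- model_bwd(model, Xl, S, fw, 2 * err / length(bi), masks)
        upd <- adam_step(model$params, grads, state, spec$learning_rate)
        model$params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + loss * length(bi)
        ep_mae <- ep_mae + sum(abs(err))
      }
      row <- data.frame(epoch = epoch, loss = ep_loss / n, mae = ep_mae / n)

      if (!is.null(validation)) {
        vm <- eval_mae_loss(model, validation)
        if (!all(is.finite(vm)))
          stop("non-finite validation loss at epoch ", epoch, call. = FALSE)
        row$val_loss <- unname(vm["loss"]); row$val_mae <- unname(vm["mae"])
        hist[[epoch]] <- row
        if (vm["mae"] < best$metric) {
          best$metric <- unname(vm["mae"])
          best$params <- model$params
          best$wait <- 0L
        } else {
          best$wait <- best$wait + 1L
          if (best$wait >= config$patience) break
        }
      } else {
        # no validation set: train for the full epoch budget, keep last weights
        hist[[epoch]] <- row
        best$params <- model$params
      }
    }
  })

  model$params <- best$params
  model$trained <- TRUE
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  rownames(model$history) <- NULL
  model
}

#' Predict occupancy rates for windowed samples
#'
#' @param object A trained `bor_forecaster`.
#' @param newdata A `window_set`.
#' @param batch_size Prediction batch size.
#' @param ... Unused.
#' @return Numeric vector of predicted rates in (0, 1), one per sample, in
#'   sample order.
#' @export
predict.bor_forecaster <- function(object, newdata, batch_size = 1024L, ...) {
  stopifnot(inherits(newdata, "window_set"))
  n <- n_samples(newdata)
  if (n == 0) return(numeric(0))
  check_dims(object, newdata)
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    bi <- start:min(start + batch_size - 1L, n)
    Xl <- x_to_list(newdata$X, bi)
    S <- if (object$fusion) newdata$S[bi, , drop = FALSE] else NULL
    out[bi] <- model_fwd(object, Xl, S)$pred
  }
  out
}

#' Persistence baseline
#'
#' Naive forecast: the last occupancy-rate value inside each input window.
#'
#' @param ws A `window_set`.
#' @return Numeric vector of predictions, one per sample.
#' @export
persistence_baseline <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  n <- n_samples(ws)
  if (n == 0) return(numeric(0))
  ws$X[, ws$window_len, ws$rate_col]
}

#' Global-mean baseline
#'
#' Predicts the mean training-set target rate for every sample.
#'
#' @param train Training `window_set` providing the mean.
#' @param ws `window_set` to predict for.
#' @return Numeric vector of identical predictions.
#' @export
global_mean_baseline <- function(train, ws) {
  stopifnot(inherits(train, "window_set"), inherits(ws, "window_set"))
  rep(mean(train$y), n_samples(ws))
}

# ---- checkpointing ----------------------------------------------------------

serialize_tree <- function(p) {
  if (is.list(p)) lapply(p, serialize_tree)
  else list(.dim = dim(p) %||% length(p), .x = as.vector(p))
}

deserialize_tree <- function(s) {
  if (!is.null(s$.x)) {
    x <- as.numeric(s$.x)
    if (length(s$.dim) == 2) matrix(x, s$.dim[[1]], s$.dim[[2]]) else x
  } else {
    lapply(s, deserialize_tree)
  }
}

#' Save / load a forecaster checkpoint
#'
#' JSON checkpoint holding the model spec manifest, dimensions and all weight
#' arrays at full precision.
#'
#' @param model A `bor_forecaster`.
#' @param path File path (`.json`).
#' @return `path` invisibly (writer); the restored `bor_forecaster` (reader).
#' @export
write_forecaster <- function(model, path) {
  stopifnot(inherits(model, "bor_forecaster"))
  doc <- list(
    spec = unclass(model$spec), fusion = model$fusion,
    n_dynamic = model$n_dynamic, n_static = model$n_static,
    trained = model$trained, params = serialize_tree(model$params)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_forecaster
#' @export
read_forecaster <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  spec <- do.call(model_spec, doc$spec)
  structure(list(spec = spec, params = deserialize_tree(doc$params),
                 fusion = doc$fusion, n_dynamic = doc$n_dynamic,
                 n_static = doc$n_static, trained = doc$trained,
                 history = NULL),
            class = "bor_forecaster")
}
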