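# Native network engine for the occupancy forecasters: LSTM / bidirectional
# LSTM layers, the attention-with-context pooling layer, dense layers,
# LeakyReLU, inverted dropout, and Adam, all as vectorised batch matrix
# operations with hand-derived backpropagation. Sequences are carried as
# lists of T matrices (batch x features). Gradients are verified against
# numerical differentiation in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

leaky_fwd <- function(x, slope) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  x
}

# dy through LeakyReLU given the pre-activation
leaky_bwd <- function(dy, pre, slope) {
  neg <- pre < 0
  dy[neg] <- dy[neg] * slope
  dy
}

glorot <- function(nin, nout) {
  l <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -l, l), nin, nout)
}

# Apply f over the leaves (numeric arrays) of parallel parameter trees.
tree_map <- function(f, ...) {
  first <- ..1
  if (is.list(first)) {
    args <- list(...)
    out <- vector("list", length(first))
    names(out) <- names(first)
    for (i in seq_along(first)) {
      out[[i]] <- do.call(tree_map, c(list(f), lapply(args, `[[`, i)))
    }
    out
  } else {
    f(...)
  }
}

tree_count <- function(p) {
  if (is.list(p)) sum(vapply(p, tree_count, numeric(1))) else length(p)
}

# ---- LSTM -------------------------------------------------------------------

lstm_init <- function(n_in, units) {
  list(Wx = glorot(n_in, 4 * units),
       Wh = glorot(units, 4 * units),
       b = rep(0, 4 * units))
}

# Xl: list of T (N x F) matrices. Returns hidden sequence and caches.
lstm_fwd <- function(Xl, p, reverse = FALSE) {
  Tn <- length(Xl)
  N <- nrow(Xl[[1]])
  U <- nrow(p$Wh)
  ord <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  h <- matrix(0, N, U)
  cs <- matrix(0, N, U)
  H <- vector("list", Tn)
  cache <- vector("list", Tn)
  bmat <- matrix(p$b, N, 4 * U, byrow = TRUE)
  for (t in ord) {
    G <- Xl[[t]] %*% p$Wx + h %*% p$Wh + bmat
    i <- sigmoid(G[, 1:U, drop = FALSE])
    f <- sigmoid(G[, U + 1:U, drop = FALSE])
    g <- tanh(G[, 2 * U + 1:U, drop = FALSE])
    o <- sigmoid(G[, 3 * U + 1:U, drop = FALSE])
    c_new <- f * cs + i * g
    tc <- tanh(c_new)
    cache[[t]] <- list(i = i, f = f, g = g, o = o,
                       c_prev = cs, tc = tc, h_prev = h)
    h <- o * tc
    cs <- c_new
    H[[t]] <- h
  }
  list(H = H, cache = cache, ord = ord)
}

lstm_bwd <- function(dH, Xl, p, fw) {
  Tn <- length(Xl)
  N <- nrow(Xl[[1]])
  U <- nrow(p$Wh)
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- p$b * 0
  dX <- vector("list", Tn)
  dh_next <- matrix(0, N, U)
  dc_next <- matrix(0, N, U)
  for (t in rev(fw$ord)) {
    cc <- fw$cache[[t]]
    dh <- dH[[t]] + dh_next
    do_ <- dh * cc$tc
    dc <- dh * cc$o * (1 - cc$tc^2) + dc_next
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dG <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(Xl[[t]], dG)
    dWh <- dWh + crossprod(cc$h_prev, dG)
    db <- db + colSums(dG)
    dX[[t]] <- dG %*% t(p$Wx)
    dh_next <- dG %*% t(p$Wh)
    dc_next <- dc * cc$f
  }
  list(dX = dX, grads = list(Wx = dWx, Wh = dWh, b = db))
}

# Recurrent layer: plain LSTM or bidirectional (concatenated directions).
rec_init <- function(n_in, units, bidirectional) {
  if (bidirectional) list(f = lstm_init(n_in, units), b = lstm_init(n_in, units))
  else lstm_init(n_in, units)
}

rec_fwd <- function(Xl, p, bidirectional) {
  if (!bidirectional) {
    fw <- lstm_fwd(Xl, p)
    list(H = fw$H, cache = fw)
  } else {
    fw <- lstm_fwd(Xl, p$f)
    bw <- lstm_fwd(Xl, p$b, reverse = TRUE)
    H <- Map(cbind, fw$H, bw$H)
    list(H = H, cache = list(f = fw, b = bw))
  }
}

rec_bwd <- function(dH, Xl, p, fwd, bidirectional) {
  if (!bidirectional) {
    lstm_bwd(dH, Xl, p, fwd$cache)
  } else {
    U <- nrow(p$f$Wh)
    dHf <- lapply(dH, function(m) m[, 1:U, drop = FALSE])
    dHb <- lapply(dH, function(m) m[, U + 1:U, drop = FALSE])
    bf <- lstm_bwd(dHf, Xl, p$f, fwd$cache$f)
    bb <- lstm_bwd(dHb, Xl, p$b, fwd$cache$b)
    list(dX = Map(`+`, bf$dX, bb$dX),
         grads = list(f = bf$grads, b = bb$grads))
  }
}

# ---- attention with context -------------------------------------------------

attn_init <- function(d) {
  list(W = glorot(d, d), b = rep(0, d), u = glorot(d, 1)[, 1])
}

#' Attention-with-context pooling of a hidden-state sequence
#'
#' Pools T hidden states into one context vector: each state is projected
#' through a tanh layer, scored against a learned context vector, the scores
#' are softmax-normalised over time, and the context is the weight-averaged
#' hidden state: `u_t = tanh(W h_t + b)`, `a_t = softmax_t(u_t . u_c)`,
#' `context = sum_t a_t h_t`. Weights are strictly positive and sum to one, so
#' the context lies in the convex hull of the hidden states.
#'
#' @param H A T x d matrix of hidden states (single sequence), or a list of T
#'   batch matrices (N x d) for batched use.
#' @param params List with `W` (d x d), `b` (length d), `u` (length d).
#' @return List with `context` (length-d vector, or N x d matrix when
#'   batched) and `weights` (length-T vector, or N x T matrix).
#' @export
attention_with_context <- function(H, params) {
  single <- is.matrix(H)
  Hl <- if (single) lapply(seq_len(nrow(H)), function(t) H[t, , drop = FALSE]) else H
  d <- ncol(Hl[[1]])
  if (!(nrow(params$W) == d && ncol(params$W) == d &&
        length(params$b) == d && length(params$u) == d))
    stop("attention parameter shapes do not match hidden dimension ", d,
         call. = FALSE)
  fw <- attn_fwd(Hl, params)
  if (single) list(context = fw$ctx[1, ], weights = fw$alpha[1, ])
  else list(context = fw$ctx, weights = fw$alpha)
}

attn_fwd <- function(Hl, p) {
  Tn <- length(Hl)
  N <- nrow(Hl[[1]])
  d <- ncol(Hl[[1]])
  U <- vector("list", Tn)
  S <- matrix(0, N, Tn)
  bmat <- matrix(p$b, N, d, byrow = TRUE)
  for (t in seq_len(Tn)) {
    U[[t]] <- tanh(Hl[[t]] %*% p$W + bmat)
    S[, t] <- U[[t]] %*% p$u
  }
  S <- S - apply(S, 1, max)   # softmax stabilisation
  E <- exp(S)
  alpha <- E / rowSums(E)
  ctx <- matrix(0, N, d)
  for (t in seq_len(Tn)) ctx <- ctx + alpha[, t] * Hl[[t]]
  list(ctx = ctx, alpha = alpha, U = U)
}

attn_bwd <- function(dctx, Hl, p, fw) {
  Tn <- length(Hl)
  N <- nrow(Hl[[1]])
  alpha <- fw$alpha
  dalpha <- matrix(0, N, Tn)
  dH <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    dalpha[, t] <- rowSums(dctx * Hl[[t]])
    dH[[t]] <- alpha[, t] * dctx
  }
  dS <- alpha * (dalpha - rowSums(alpha * dalpha))
  dW <- p$W * 0; db <- p$b * 0; du <- p$u * 0
  for (t in seq_len(Tn)) {
    dU <- tcrossprod(dS[, t], p$u)
    dA <- dU * (1 - fw$U[[t]]^2)
    dW <- dW + crossprod(Hl[[t]], dA)
    db <- db + colSums(dA)
    du <- du + colSums(dS[, t] * fw$U[[t]])
    dH[[t]] <- dH[[t]] + dA %*% t(p$W)
  }
  list(dH = dH, grads = list(W = dW, b = db, u = du))
}

# ---- dense / dropout --------------------------------------------------------

dense_init <- function(n_in, n_out) {
  list(W = glorot(n_in, n_out), b = rep(0, n_out))
}

dense_fwd <- function(X, p) sweep(X %*% p$W, 2, p$b, "+")

dense_bwd <- function(dY, X, p) {
  list(dX = dY %*% t(p$W),
       grads = list(W = crossprod(X, dY), b = colSums(dY)))
}

# Inverted dropout: mask drawn at train time, activations rescaled so the
# expected value matches inference (where dropout is a no-op).
dropout_mask <- function(n, m, rate) {
  if (rate <= 0) return(NULL)
  matrix(stats::rbinom(n * m, 1L, 1 - rate) / (1 - rate), n, m)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_map(function(p) p * 0, params),
       v = tree_map(function(p) p * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- tree_map(function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
                     params, state$m, state$v)
  list(params = params, state = state)
}

# ---- full-model forward / backward -----------------------------------------

# Dynamic stack shared by the base and fusion architectures:
# recurrent -> LeakyReLU -> recurrent -> LeakyReLU -> attention -> LeakyReLU.
dyn_stack_fwd <- function(Xl, params, spec) {
  bi <- spec$architecture == "bilstm"
  sl <- spec$leaky_slope
  r1 <- rec_fwd(Xl, params$l1, bi)
  A1 <- lapply(r1$H, leaky_fwd, slope = sl)
  r2 <- rec_fwd(A1, params$l2, bi)
  A2 <- lapply(r2$H, leaky_fwd, slope = sl)
  at <- attn_fwd(A2, params$att)
  A3 <- leaky_fwd(at$ctx, sl)
  list(out = A3, r1 = r1, A1 = A1, r2 = r2, A2 = A2, at = at)
}

dyn_stack_bwd <- function(dA3, Xl, params, spec, fw) {
  bi <- spec$architecture == "bilstm"
  sl <- spec$leaky_slope
  dctx <- leaky_bwd(dA3, fw$at$ctx, sl)
  ab <- attn_bwd(dctx, fw$A2, params$att, fw$at)
  dH2 <- Map(function(d, pre) leaky_bwd(d, pre, sl), ab$dH, fw$r2$H)
  b2 <- rec_bwd(dH2, fw$A1, params$l2, fw$r2, bi)
  dH1 <- Map(function(d, pre) leaky_bwd(d, pre, sl), b2$dX, fw$r1$H)
  b1 <- rec_bwd(dH1, Xl, params$l1, fw$r1, bi)
  list(grads = list(l1 = b1$grads, l2 = b2$grads, att = ab$grads))
}

# Forward pass for a whole model; masks (static-branch dropout) are NULL at
# inference time.
model_fwd <- function(model, Xl, S = NULL, masks = NULL) {
  p <- model$params
  spec <- model$spec
  dyn <- dyn_stack_fwd(Xl, p, spec)
  if (!model$fusion) {
    z <- dense_fwd(dyn$out, p$head)
    pred <- sigmoid(z)
    return(list(pred = as.vector(pred), dyn = dyn, head_in = dyn$out, z = z))
  }
  if (is.null(S)) stop("fusion model requires a static matrix", call. = FALSE)
  sl <- spec$leaky_slope
  z1 <- dense_fwd(S, p$s1); a1 <- leaky_fwd(z1, sl)
  d1 <- if (is.null(masks)) a1 else a1 * masks[[1]]
  z2 <- dense_fwd(d1, p$s2); a2 <- leaky_fwd(z2, sl)
  d2 <- if (is.null(masks)) a2 else a2 * masks[[2]]
  head_in <- cbind(dyn$out, d2)
  z <- dense_fwd(head_in, p$head)
  pred <- sigmoid(z)
  list(pred = as.vector(pred), dyn = dyn, head_in = head_in, z = z,
       z1 = z1, d1 = d1, z2 = z2)
}

# Backward pass from dL/dpred; returns the gradient tree matching params.
model_bwd <- function(model, Xl, S, fw, dpred, masks = NULL) {
  p <- model$params
  spec <- model$spec
  pred <- sigmoid(fw$z)
  dz <- matrix(dpred * pred * (1 - pred), ncol = 1)
  hb <- dense_bwd(dz, fw$head_in, p$head)
  if (!model$fusion) {
    db <- dyn_stack_bwd(hb$dX, Xl, p, spec, fw$dyn)
    return(c(db$grads, list(head = hb$grads)))
  }
  d_dyn_out <- ncol(fw$dyn$out)
  dA3 <- hb$dX[, seq_len(d_dyn_out), drop = FALSE]
  dD2 <- hb$dX[, d_dyn_out + seq_len(ncol(fw$head_in) - d_dyn_out), drop = FALSE]
  db <- dyn_stack_bwd(dA3, Xl, p, spec, fw$dyn)
  sl <- spec$leaky_slope
  dA2 <- if (is.null(masks)) dD2 else dD2 * masks[[2]]
  dz2 <- leaky_bwd(dA2, fw$z2, sl)
  s2b <- dense_bwd(dz2, fw$d1, p$s2)
  dA1 <- if (is.null(masks)) s2b$dX else s2b$dX * masks[[1]]
  dz1 <- leaky_bwd(dA1, fw$z1, sl)
  s1b <- dense_bwd(dz1, S, p$s1)
  c(db$grads, list(s1 = s1b$grads, s2 = s2b$grads, head = hb$grads))
}

# Slice a window-set X array into the list-of-timesteps batch layout.
x_to_list <- function(X, idx = NULL) {
  if (!is.null(idx)) X <- X[idx, , , drop = FALSE]
  N <- dim(X)[1]; Tn <- dim(X)[2]; Fd <- dim(X)[3]
  lapply(seq_len(Tn), function(t) matrix(X[, t, ], N, Fd))
}
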