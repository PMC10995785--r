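# Shared fixtures and independent oracles for the test suite.

# Tiny deterministic hospital: 2 wards x 2 rooms, capacities 4, 2, 3, 1.
tiny_layout <- function() {
  lay <- build_layout(2, 2, 1, seed = 1)
  lay$capacity[] <- c(4L, 2L, 3L, 1L)
  lay
}

tiny_profiles <- function(lay = tiny_layout()) {
  sample_static_profiles(lay, rep(0.3, 13), n_room_codes = 3, seed = 5)
}

tiny_config <- function(..., start = "2022-03-01", end = "2022-03-31", seed = 42) {
  sim_config(start, end, ..., seed = seed)
}

# Build an hourly record block for one bed-day by hand: `occ_hours` of the 24
# hours carry the "patient present" (missing) status.
hand_records <- function(date, ward, room, bed, occ_hours) {
  status <- rep(c("admittable", "discharge"), length.out = 24)
  if (occ_hours > 0) status[seq_len(occ_hours)] <- NA
  data.table::data.table(
    timestamp = sprintf("%sT%02d:00:00", date, 0:23),
    ward = ward, room = room, bed = bed, status = status
  )
}

# Independent brute-force reference for the four forecast metrics.
ref_metrics <- function(y, p) {
  n <- length(y)
  sae <- 0; sse <- 0
  for (i in seq_len(n)) {
    sae <- sae + abs(y[i] - p[i])
    sse <- sse + (y[i] - p[i])^2
  }
  ybar <- sum(y) / n
  sst <- 0
  for (i in seq_len(n)) sst <- sst + (y[i] - ybar)^2
  list(mae = sae / n, mse = sse / n, rmse = sqrt(sse / n),
       r2 = 1 - sse / sst)
}

# Exact central binomial 99% interval for a pooled proportion.
binom99 <- function(n, p) {
  c(qbinom(0.005, n, p), qbinom(0.995, n, p)) / n
}

# Closed-form trainable-parameter counts for the layer stack.
count_lstm <- function(n_in, units) 4 * units * (n_in + units + 1)
count_base_params <- function(arch, units, n_features) {
  dirs <- if (arch == "bilstm") 2 else 1
  d <- dirs * units
  l1 <- dirs * count_lstm(n_features, units)
  l2 <- dirs * count_lstm(d, units)
  att <- d * d + d + d
  head <- d + 1
  l1 + l2 + att + head
}
count_fusion_params <- function(arch, units, n_dynamic, n_static, widths) {
  dirs <- if (arch == "bilstm") 2 else 1
  d <- dirs * units
  stack <- dirs * count_lstm(n_dynamic, units) +
    dirs * count_lstm(d, units) + d * d + 2 * d
  s1 <- (n_static + 1) * widths[1]
  s2 <- (widths[1] + 1) * widths[2]
  head <- d + widths[2] + 1
  stack + s1 + s2 + head
}

# Random windowed sample set (direct construction, bypassing the simulator)
# for forecaster-level unit tests.
random_window_set <- function(n = 40, L = 5, Fd = 4, n_static = 0, seed = 1) {
  set.seed(seed)
  dyn_cols <- c(paste0("f", seq_len(Fd - 1)), "rate")
  X <- array(runif(n * L * Fd), c(n, L, Fd), dimnames = list(NULL, NULL, dyn_cols))
  S <- if (n_static > 0) matrix(runif(n * n_static), n, n_static) else NULL
  structure(
    list(X = X, S = S, y = runif(n),
         entity = rep("E1", n),
         target_date = as.Date("2022-01-01") + seq_len(n),
         dynamic_cols = dyn_cols,
         static_cols = if (n_static > 0) paste0("s", seq_len(n_static)),
         rate_col = Fd, window_len = L, horizon = 1L),
    class = "window_set"
  )
}

# A small encoded dataset built through the real pipeline, cached per session.
small_ward_dataset <- function() {
  if (is.null(.fixture_env$ward_ds)) {
    lay <- build_layout(3, 4, c(2, 6), seed = 9)
    prof <- sample_static_profiles(lay, rep(0.2, 13), seed = 9)
    cfg <- sim_config("2022-01-01", "2022-06-30", mu = 0.3,
                      beta_dow = c(.4, .2, 0, -.1, -.3, -.6, -.7),
                      rho = 0.4, sigma = 0.3, seed = 31)
    daily <- simulate_daily_states(lay, prof, cfg)
    tab <- occupancy_table(daily, "ward")
    .fixture_env$ward_ds <- encode_and_normalize(
      tab, "ward", train_range = c("2022-01-01", "2022-04-30"))
  }
  .fixture_env$ward_ds
}
.fixture_env <- new.env()
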