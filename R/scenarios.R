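# Pinned synthetic study scenarios. These fix the simulated hospital
# configurations under which the forecasters' learnability and fusion-benefit
# properties are evaluated, so tests, the acceptance script and the analysis
# scripts all run under identical conditions.

#' Weekly-pattern ward scenario
#'
#' Twenty wards of 400 beds (20 rooms x 20 beds) over 400 days with a strong
#' deterministic day-of-week occupancy pattern and no latent noise, so the
#' only stochasticity is binomial bed-count sampling (rate-scale standard
#' deviation about 0.025 at half occupancy). Days 1-280 are the training
#' range, 281-340 validation, 341-400 test.
#'
#' @param seed Simulation seed.
#' @param window_len Window length for the returned samples (default 7).
#' @return List with `layout`, `config`, `table` (ward-level daily occupancy),
#'   `dataset` (encoded ward variant), `split` (the [split_spec()]), and
#'   `samples` (a chronological split of the windowed samples).
#' @export
scenario_weekly_wards <- function(seed = 1L, window_len = 7L) {
  layout <- build_layout(20, 20, 20, seed = 104729L)
  profiles <- sample_static_profiles(layout, rep(0, 13), seed = 104729L)
  start <- as.Date("2021-01-01")
  days <- 400L
  config <- sim_config(
    start, start + days - 1L, mu = 0.2,
    beta_dow = c(0.9, 0.5, 0.1, -0.1, -0.5, -1.0, -1.2),
    rho = 0, sigma = 0, seed = seed
  )
  daily <- simulate_daily_states(layout, profiles, config)
  tab <- occupancy_table(daily, "ward")
  bounds <- start + c(0L, 279L, 280L, 339L, 340L, days - 1L)
  spl <- split_spec(bounds[1:2], bounds[3:4], bounds[5:6])
  dataset <- encode_and_normalize(tab, "ward", train_range = spl$train)
  ws <- make_windows(dataset, window_len)
  list(layout = layout, config = config, table = tab, dataset = dataset,
       split = spl, samples = chronological_split(ws, spl))
}

#' Static-amplitude room scenario
#'
#' Forty rooms of 15 beds over 400 days where the first static flag (drawn
#' with probability 0.5) scales the weekly occupancy amplitude: flagged rooms
#' have their day-of-week effect damped by 90% (`beta_dow_mod = -0.9`) and a
#' shifted baseline (`gamma[1] = 0.8`). Moderate autocorrelated latent noise
#' (`rho = 0.5`, `sigma = 0.15`) is added. The static attributes therefore
#' carry genuine predictive information beyond the dynamic history, which is
#' the regime where a static-fusion model can improve on a dynamic-only one.
#'
#' @param seed Simulation seed.
#' @param window_len Window length (default 7).
#' @return List with `layout`, `profiles`, `config`, `table` (room-level),
#'   `datasets` (encoded `room` and `room_static` variants), `split`, and
#'   `samples` (list of chronological splits per variant).
#' @export
scenario_static_amplitude <- function(seed = 1L, window_len = 7L) {
  layout <- build_layout(4, 10, 15, seed = 7919L)
  profiles <- sample_static_profiles(layout, c(0.5, rep(0.15, 12)),
                                     n_room_codes = 6, seed = 7919L)
  start <- as.Date("2021-01-01")
  days <- 400L
  config <- sim_config(
    start, start + days - 1L, mu = -0.2,
    beta_dow = c(1.2, 0.8, 0.2, -0.2, -0.8, -1.4, -1.6),
    gamma = c(0.8, rep(0, 12)), beta_dow_mod = -0.9,
    rho = 0.5, sigma = 0.15, seed = seed
  )
  daily <- simulate_daily_states(layout, profiles, config)
  tab <- occupancy_table(daily, "room")
  bounds <- start + c(0L, 279L, 280L, 339L, 340L, days - 1L)
  spl <- split_spec(bounds[1:2], bounds[3:4], bounds[5:6])
  datasets <- list(
    room = encode_and_normalize(tab, "room", train_range = spl$train),
    room_static = encode_and_normalize(tab, "room_static",
                                       static_profiles = profiles,
                                       train_range = spl$train)
  )
  samples <- lapply(datasets, function(d)
    chronological_split(make_windows(d, window_len), spl))
  list(layout = layout, profiles = profiles, config = config, table = tab,
       datasets = datasets, split = spl, samples = samples)
}
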