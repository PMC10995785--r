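# Synthetic hospital generator: hierarchical ward/room/bed layout, static room
# attributes, and a latent-logit occupancy process with weekly, seasonal,
# holiday and static-attribute effects plus AR(1) temporal autocorrelation.
# Emits hourly bed-level status records matching the schema of real
# bed-management extracts so the whole downstream pipeline can be exercised
# without access to any hospital data.

#' Names of the 13 binary static room attributes
#'
#' Capability flags recorded per room in the static room table: nuclear
#' medicine, sterile, isolation, EEG testing, observation, kidney transplant,
#' liver transplant, sub-ICU, special, small single, short-term, psychiatry
#' double and psychiatry open rooms. Together with the categorical room grade
#' code they form the 14 static room variables.
#'
#' @export
STATIC_FLAGS <- c(
  "nuclear", "sterile", "isolation", "eeg_testing", "observation",
  "kidney", "liver", "sub_icu", "special", "small_single",
  "short_term", "psy_double", "psy_open"
)

#' Build a hospital ward/room/bed layout
#'
#' Creates a hierarchy of wards, rooms nested in wards, and per-room integer
#' bed capacities. Ward capacity is by construction the sum of its room
#' capacities.
#'
#' @param n_wards Number of wards (>= 1).
#' @param rooms_per_ward Rooms per ward: a fixed integer, a length-2 inclusive
#'   range sampled uniformly, or a `function(n)` returning integers >= 1.
#' @param capacity_dist Beds per room, same spec forms as `rooms_per_ward`.
#' @param seed Integer seed; the same seed always yields the same layout.
#' @return A `hospital_layout`: list with `wards` (character), `rooms` (named
#'   list ward -> room ids), `capacity` (named integer per room) and `ward_of`
#'   (named character, room -> ward).
#' @examples
#' lay <- build_layout(2, 3, 4, seed = 1)
#' sum(lay$capacity)  # 2 wards x 3 rooms x 4 beds = 24
#' @export
build_layout <- function(n_wards, rooms_per_ward, capacity_dist, seed = 1L) {
  if (!is.numeric(n_wards) || length(n_wards) != 1 || n_wards < 1)
    stop("n_wards must be a single integer >= 1", call. = FALSE)
  n_wards <- as.integer(n_wards)
  with_seed(seed, {
    wards <- sprintf("W%02d", seq_len(n_wards))
    nrooms <- draw_int_spec(rooms_per_ward, n_wards, "rooms_per_ward")
    rooms <- lapply(seq_len(n_wards), function(i) {
      sprintf("%sR%02d", wards[i], seq_len(nrooms[i]))
    })
    names(rooms) <- wards
    room_ids <- unlist(rooms, use.names = FALSE)
    capacity <- draw_int_spec(capacity_dist, length(room_ids), "capacity")
    names(capacity) <- room_ids
    ward_of <- rep(wards, nrooms)
    names(ward_of) <- room_ids
    structure(
      list(wards = wards, rooms = rooms, capacity = capacity, ward_of = ward_of),
      class = "hospital_layout"
    )
  })
}

#' @export
print.hospital_layout <- function(x, ...) {
  cat("<hospital_layout> ", length(x$wards), " wards, ",
      length(x$capacity), " rooms, ", sum(x$capacity), " beds\n", sep = "")
  invisible(x)
}

#' Ward capacities of a layout
#'
#' @param layout A `hospital_layout`.
#' @return Named integer vector of total beds per ward.
#' @export
ward_capacity <- function(layout) {
  stopifnot(inherits(layout, "hospital_layout"))
  vapply(layout$rooms, function(r) sum(layout$capacity[r]), integer(1))
}

#' Sample static room attribute profiles
#'
#' Draws one static profile per room: a categorical room grade code plus the 13
#' binary capability flags of [STATIC_FLAGS], each flag an independent
#' Bernoulli draw.
#'
#' @param layout A `hospital_layout`.
#' @param flag_probabilities 13 probabilities in `[0, 1]`, one per flag
#'   (recycled if a single value is given).
#' @param n_room_codes Number of distinct room grade codes (default 34).
#' @param seed Integer seed.
#' @return `data.table` with columns `room`, `ward`, `room_code` and the 13
#'   flag columns, one row per room.
#' @export
sample_static_profiles <- function(layout, flag_probabilities = rep(0.1, 13),
                                   n_room_codes = 34L, seed = 1L) {
  stopifnot(inherits(layout, "hospital_layout"))
  if (length(flag_probabilities) == 1)
    flag_probabilities <- rep(flag_probabilities, 13)
  if (length(flag_probabilities) != 13)
    stop("flag_probabilities must have length 13 (one per static flag)", call. = FALSE)
  if (any(flag_probabilities < 0 | flag_probabilities > 1))
    stop("flag_probabilities must lie in [0, 1]", call. = FALSE)
  if (n_room_codes < 1) stop("n_room_codes must be >= 1", call. = FALSE)
  rooms <- names(layout$capacity)
  n <- length(rooms)
  with_seed(seed, {
    prof <- data.table::data.table(
      room = rooms,
      ward = unname(layout$ward_of[rooms]),
      room_code = sprintf("G%02d", sample.int(n_room_codes, n, replace = TRUE))
    )
    for (k in seq_along(STATIC_FLAGS)) {
      prof[, (STATIC_FLAGS[k]) := stats::rbinom(n, 1L, flag_probabilities[k])]
    }
    prof[]
  })
}

#' Simulation configuration for the occupancy process
#'
#' Bundles the latent-logit occupancy model parameters. For room r on day t,
#' the latent logit is
#' `z = mu + a_r * beta_dow[dow(t)] + beta_season * sin(2*pi*doy(t)/365.25) +
#'  beta_holiday * 1(holiday) + sum(gamma * flags_r) + e_rt`,
#' where `a_r = 1 + beta_dow_mod * flag1_r` lets the first static flag scale
#' the weekly amplitude, and `e_rt = rho * e_r(t-1) + N(0, sigma)` is an AR(1)
#' noise process (initialised from its stationary distribution). The occupied
#' bed count is `Binomial(capacity_r, plogis(z))`.
#'
#' @param start,end Calendar dates (coerced with [as.Date()]), `start <= end`.
#' @param mu Base occupancy logit.
#' @param beta_dow Length-7 day-of-week effects, indexed by ISO weekday
#'   (1 = Monday ... 7 = Sunday).
#' @param beta_season Seasonal (annual sine) amplitude on the logit scale.
#' @param beta_holiday Additive holiday effect on the logit scale.
#' @param gamma Length-13 static-attribute effects, aligned with [STATIC_FLAGS].
#' @param beta_dow_mod Multiplicative modulation of the weekly effect by the
#'   first static flag (0 disables; -1 flattens the weekly pattern for flagged
#'   rooms).
#' @param rho AR(1) autocorrelation of the latent noise, in `[0, 1)`.
#' @param sigma AR(1) innovation standard deviation, >= 0.
#' @param holidays Vector of holiday dates (any [as.Date()] input).
#' @param seed Integer seed controlling all randomness of the simulation.
#' @return A `sim_config` list.
#' @export
sim_config <- function(start, end, mu = 0, beta_dow = rep(0, 7),
                       beta_season = 0, beta_holiday = 0,
                       gamma = rep(0, 13), beta_dow_mod = 0,
                       rho = 0, sigma = 0,
                       holidays = as.Date(character()), seed = 1L) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end) || start > end)
    stop("invalid date range: need start <= end", call. = FALSE)
  if (length(beta_dow) != 7) stop("beta_dow must have length 7", call. = FALSE)
  if (length(gamma) != 13) stop("gamma must have length 13", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(
    list(start = start, end = end, mu = mu, beta_dow = beta_dow,
         beta_season = beta_season, beta_holiday = beta_holiday,
         gamma = gamma, beta_dow_mod = beta_dow_mod,
         rho = rho, sigma = sigma,
         holidays = as.Date(holidays), seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate per-room daily occupied bed counts
#'
#' Draws the latent-logit occupancy process described in [sim_config()] for
#' every room and day of the configured range. Deterministic given
#' `config$seed`.
#'
#' @param layout A `hospital_layout`.
#' @param profiles Static profiles from [sample_static_profiles()] (row order
#'   is aligned to the layout's rooms internally).
#' @param config A `sim_config`.
#' @return `data.table` with columns `date`, `ward`, `room`, `capacity`,
#'   `occupied`, ordered by room then date.
#' @export
simulate_daily_states <- function(layout, profiles, config) {
  stopifnot(inherits(layout, "hospital_layout"), inherits(config, "sim_config"))
  rooms <- names(layout$capacity)
  prof <- data.table::as.data.table(profiles)
  if (!all(rooms %in% prof$room))
    stop("profiles must cover every room in the layout", call. = FALSE)
  prof <- prof[match(rooms, prof$room)]
  flags <- as.matrix(prof[, STATIC_FLAGS, with = FALSE])
  static_eff <- as.vector(flags %*% config$gamma)
  amp <- 1 + config$beta_dow_mod * flags[, 1]

  dates <- seq(config$start, config$end, by = "day")
  Tn <- length(dates); R <- length(rooms)
  dow <- as.integer(format(dates, "%u"))
  doy <- as.integer(format(dates, "%j"))
  season <- config$beta_season * sin(2 * pi * doy / 365.25)
  hol <- config$beta_holiday * as.numeric(dates %in% config$holidays)
  cap <- unname(layout$capacity[rooms])

  with_seed(config$seed, {
    # AR(1) latent noise, rooms x days, stationary initial state
    e <- matrix(0, R, Tn)
    if (config$sigma > 0) {
      e[, 1] <- stats::rnorm(R, 0, config$sigma / sqrt(1 - config$rho^2))
      if (Tn > 1) {
        for (t in 2:Tn) {
          e[, t] <- config$rho * e[, t - 1] + stats::rnorm(R, 0, config$sigma)
        }
      }
    }
    z <- config$mu + outer(amp, config$beta_dow[dow]) +
      matrix(season + hol, R, Tn, byrow = TRUE) + static_eff + e
    occ <- matrix(
      stats::rbinom(R * Tn, size = rep(cap, Tn), prob = stats::plogis(as.vector(z))),
      R, Tn
    )
    out <- data.table::data.table(
      date = rep(dates, each = R),
      ward = rep(unname(layout$ward_of[rooms]), Tn),
      room = rep(rooms, Tn),
      capacity = rep(cap, Tn),
      occupied = as.integer(as.vector(occ))
    )
    data.table::setorder(out, room, date)
    out[]
  })
}

#' Expand daily room states to hourly bed-level status records
#'
#' Emits 24 records per bed per day. Within a day the first `occupied` beds of
#' a room carry the "patient present" status (encoded as a missing status
#' field, as in the source extracts) for all 24 hours; the remaining beds carry
#' `"admittable"` or `"discharge"`. Status is constant within a day, so
#' re-aggregating the stream recovers the daily counts exactly.
#'
#' @param daily Output of [simulate_daily_states()].
#' @param layout A `hospital_layout` (capacities are taken from `daily`; the
#'   layout is accepted for interface symmetry and sanity checks).
#' @param hours Integer hours to emit per day (default `0:23`).
#' @return `data.table` with columns `timestamp` (ISO-8601 character), `ward`,
#'   `room`, `bed`, `status` (`NA` = patient present), ordered by room, bed,
#'   timestamp. Row count = total beds x days x `length(hours)`.
#' @export
expand_to_hourly <- function(daily, layout = NULL, hours = 0:23) {
  d <- data.table::as.data.table(daily)
  if (!is.null(layout)) {
    stopifnot(inherits(layout, "hospital_layout"))
    if (!all(d$room %in% names(layout$capacity)))
      stop("daily states reference rooms absent from the layout", call. = FALSE)
  }
  beds <- d[, {
    i <- seq_len(capacity)
    list(bed = sprintf("%sB%02d", room, i),
         status = ifelse(i <= occupied, NA_character_,
                         ifelse(i %% 2L == 1L, "admittable", "discharge")))
  }, by = .(date, ward, room, capacity, occupied)]
  out <- beds[rep(seq_len(.N), each = length(hours))]
  out[, hour := rep(hours, length.out = .N)]
  out[, timestamp := sprintf("%sT%02d:00:00", as.character(date), hour)]
  out <- out[, .(timestamp, ward, room, bed, status)]
  data.table::setorder(out, room, bed, timestamp)
  out[]
}

#' Write / read hourly bed status records as CSV
#'
#' Schema: `timestamp,ward,room,bed,status` with ISO-8601 timestamps; an empty
#' status field encodes "patient present". A `.gz` extension triggers gzip
#' compression.
#'
#' @param records `data.table` of bed status records.
#' @param path Output file path.
#' @return `path`, invisibly (writer); the records `data.table` (reader).
#' @export
write_bed_records <- function(records, path) {
  data.table::fwrite(records, path, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_bed_records
#' @export
read_bed_records <- function(path) {
  cls <- list(character = c("timestamp", "ward", "room", "bed", "status"))
  out <- if (grepl("\\.gz$", path) && !requireNamespace("R.utils", quietly = TRUE)) {
    if (nzchar(Sys.which("gzip"))) {
      data.table::fread(cmd = paste("gzip -dc", shQuote(path)),
                        na.strings = "", colClasses = cls)
    } else {
      data.table::as.data.table(
        utils::read.csv(gzfile(path), colClasses = "character",
                        na.strings = ""))
    }
  } else {
    data.table::fread(path, na.strings = "", colClasses = cls)
  }
  out[]
}

#' Write / read static room profiles as CSV
#'
#' One row per room with the 14 static attribute columns (room grade code plus
#' 13 binary flags).
#'
#' @param profiles Static profile `data.table`.
#' @param path File path.
#' @return `path` invisibly (writer); the profiles `data.table` (reader).
#' @export
write_static_profiles <- function(profiles, path) {
  data.table::fwrite(profiles, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_static_profiles
#' @export
read_static_profiles <- function(path) {
  data.table::fread(path)[]
}

#' Korean public holiday calendar fixture
#'
#' Dates of the eight recurring Korean public holiday types (New Year-period
#' observances excluded by the study window: Chuseok, Hangeul Proclamation Day,
#' Children's Day, National Liberation Day, Memorial Day, Buddha's Birthday,
#' Independence Movement Day, Constitution Day) falling between 2020-05-27 and
#' 2022-11-21 — 27 days in all. Shipped as a plain-text fixture; any other
#' date set can be supplied wherever a holiday calendar is accepted.
#'
#' @return Sorted `Date` vector of length 27.
#' @export
korean_holidays <- function() {
  path <- system.file("extdata", "holidays_kr_2020_2022.txt", package = "borcast")
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  sort(as.Date(lines[nzchar(lines)]))
}
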