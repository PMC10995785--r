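# Preprocessing: hourly bed-level records -> daily occupancy tables at ward or
# room level, calendar-derived date features, and encoded/normalized model
# datasets (ward, room, room+static variants).

#' Impute the bed occupancy indicator from the recorded status
#'
#' The bed-status field has two recorded states, `"admittable"` and
#' `"discharge"`; a missing (or empty) status means a patient is present.
#' Missing maps to 1 (occupied), both recorded states map to 0.
#'
#' @param status Character vector of statuses (`NA` or `""` = patient present).
#' @return Integer vector of 0/1 occupancy indicators.
#' @examples
#' impute_bed_status(c(NA, "admittable", "discharge"))  # 1 0 0
#' @export
impute_bed_status <- function(status) {
  occ <- ifelse(is.na(status) | status == "", 1L,
                ifelse(status %in% c("admittable", "discharge"), 0L, NA_integer_))
  if (anyNA(occ)) {
    bad <- unique(status[!is.na(status) & is.na(occ)])
    stop("unrecognized bed status value(s): ",
         paste(shQuote(bad), collapse = ", "), call. = FALSE)
  }
  occ
}

#' Derive calendar features for dates
#'
#' Year, month, ISO week-of-year (1-53), day-of-month, ISO weekday
#' (1 = Monday ... 7 = Sunday) and a 0/1 holiday flag set by membership in the
#' supplied calendar (weekends are not holidays; weekday already encodes them).
#'
#' @param dates Vector coercible with [as.Date()].
#' @param holidays Holiday calendar (dates).
#' @return `data.table` with columns `date`, `year`, `month`, `week`, `day`,
#'   `weekday`, `holiday`.
#' @export
derive_date_features <- function(dates, holidays = as.Date(character())) {
  d <- as.Date(dates)
  holidays <- as.Date(holidays)
  data.table::data.table(
    date = d,
    year = as.integer(format(d, "%Y")),
    month = as.integer(format(d, "%m")),
    week = as.integer(format(d, "%V")),
    day = as.integer(format(d, "%d")),
    weekday = as.integer(format(d, "%u")),
    holiday = as.integer(d %in% holidays)
  )
}

#' Aggregate hourly bed records to a daily occupancy table
#'
#' Reduces each bed's 24 hourly 0/1 indicators to a daily occupancy (mean over
#' the day rounded half-up, or a single snapshot hour), sums occupied beds to
#' the requested entity level, and divides by capacity to get the occupancy
#' rate. Ward rows are the capacity-weighted aggregate of their rooms.
#'
#' @param records Bed status records (`timestamp`, `ward`, `room`, `bed`,
#'   `status`), covering whole days.
#' @param layout A `hospital_layout` providing capacities.
#' @param level `"room"` or `"ward"`.
#' @param holidays Holiday calendar for the date features.
#' @param daily_rule `"mean"` (default): daily mean of the 24 hourly
#'   indicators, rounded half-up; `"snapshot"`: the indicator at
#'   `snapshot_hour`.
#' @param snapshot_hour Hour used by the snapshot rule.
#' @return A daily occupancy table: `data.table` with `date`, `entity`,
#'   `level`, `capacity`, `occupied`, `rate` and the [derive_date_features()]
#'   columns, one row per entity-day, ordered by entity then date.
#' @export
aggregate_daily <- function(records, layout, level = c("room", "ward"),
                            holidays = as.Date(character()),
                            daily_rule = c("mean", "snapshot"),
                            snapshot_hour = 0L) {
  level <- match.arg(level)
  daily_rule <- match.arg(daily_rule)
  stopifnot(inherits(layout, "hospital_layout"))
  rec <- data.table::as.data.table(records)

  unknown <- setdiff(unique(rec$room), names(layout$capacity))
  if (length(unknown))
    stop("records reference room(s) not in the layout: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)

  rec[, date := as.Date(substr(timestamp, 1, 10))]
  rec[, occ := impute_bed_status(status)]

  if (daily_rule == "mean") {
    bed_day <- rec[, .(n_hours = .N, m = mean(occ)), by = .(date, ward, room, bed)]
    short <- bed_day[n_hours != 24L]
    if (nrow(short)) {
      ex <- short[, sprintf("(%s, %s: %d h)", bed, date, n_hours)]
      stop("incomplete hourly coverage for ", nrow(short), " bed-day(s): ",
           paste(utils::head(ex, 5), collapse = ", "), call. = FALSE)
    }
    bed_day[, occ_day := as.integer(round_half_up(m))]
  } else {
    rec[, hour := as.integer(substr(timestamp, 12, 13))]
    bed_day <- rec[hour == snapshot_hour,
                   .(occ_day = as.integer(occ[1])), by = .(date, ward, room, bed)]
    if (nrow(bed_day) == 0)
      stop("no records at snapshot hour ", snapshot_hour, call. = FALSE)
  }

  room_day <- bed_day[, .(occupied = sum(occ_day)), by = .(date, ward, room)]
  room_day[, capacity := unname(layout$capacity[room])]

  if (level == "room") {
    out <- room_day[, .(date, entity = room, level = "room", capacity, occupied)]
  } else {
    wc <- ward_capacity(layout)
    out <- room_day[, .(capacity = unname(wc[ward[1]]), occupied = sum(occupied)),
                    by = .(date, ward)]
    out <- out[, .(date, entity = ward, level = "ward", capacity, occupied)]
  }
  out[, rate := occupied / capacity]
  feats <- derive_date_features(out$date, holidays)
  out <- cbind(out, feats[, !"date"])
  data.table::setorder(out, entity, date)
  out[]
}

#' Build a daily occupancy table directly from simulated daily states
#'
#' Equivalent to [expand_to_hourly()] followed by [aggregate_daily()], without
#' materialising the hourly stream; useful for large simulations where the
#' hourly records would exist only to be re-aggregated.
#'
#' @param daily Output of [simulate_daily_states()].
#' @param level `"room"` or `"ward"`.
#' @param holidays Holiday calendar.
#' @return A daily occupancy table (same schema as [aggregate_daily()]).
#' @export
occupancy_table <- function(daily, level = c("room", "ward"),
                            holidays = as.Date(character())) {
  level <- match.arg(level)
  d <- data.table::as.data.table(daily)
  if (level == "room") {
    out <- d[, .(date, entity = room, level = "room", capacity, occupied)]
  } else {
    out <- d[, .(capacity = sum(capacity), occupied = sum(occupied)),
             by = .(date, ward)]
    out <- out[, .(date, entity = ward, level = "ward", capacity, occupied)]
  }
  out[, rate := occupied / capacity]
  feats <- derive_date_features(out$date, holidays)
  out <- cbind(out, feats[, !"date"])
  data.table::setorder(out, entity, date)
  out[]
}

# ---- encoding & normalization ----------------------------------------------

yn_to_int <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  up <- toupper(trimws(as.character(x)))
  out <- ifelse(up %in% c("Y", "YES", "1"), 1L,
                ifelse(up %in% c("N", "NO", "0"), 0L, NA_integer_))
  if (anyNA(out)) stop("flag values must be Y/N or 0/1", call. = FALSE)
  out
}

# Ordinal encoding against a stable sorted vocabulary; unseen values map to
# the reserved code 0 with a message.
ordinal_encode <- function(x, vocab = NULL, what = "value") {
  x <- as.character(x)
  if (is.null(vocab)) vocab <- sort(unique(x))
  code <- match(x, vocab)
  if (anyNA(code)) {
    message(sum(is.na(code)), " ", what,
            "(s) unseen in the training vocabulary mapped to the reserved code 0")
    code[is.na(code)] <- 0L
  }
  list(code = as.integer(code), vocab = vocab)
}

minmax_fit <- function(dt, cols) {
  sc <- lapply(cols, function(cl) {
    v <- dt[[cl]]
    lo <- min(v); hi <- max(v)
    if (hi == lo) message("constant column '", cl, "' scaled to all zeros")
    c(min = lo, range = hi - lo)
  })
  names(sc) <- cols
  sc
}

minmax_apply <- function(dt, scaler) {
  for (cl in names(scaler)) {
    p <- scaler[[cl]]
    dt[[cl]] <- if (p["range"] == 0) rep(0, nrow(dt)) else
      (dt[[cl]] - p["min"]) / p["range"]
  }
  dt
}

minmax_invert <- function(dt, scaler) {
  for (cl in names(scaler)) {
    p <- scaler[[cl]]
    dt[[cl]] <- dt[[cl]] * p["range"] + p["min"]
  }
  dt
}

#' Encode and normalize a daily occupancy table into a model dataset
#'
#' Produces one of the study's dataset variants: `"ward"` and `"room"` carry
#' the entity abbreviation, date features, holiday flag, capacity, occupied
#' count and occupancy rate; `"room_static"` adds the 14 static room variables.
#' Categorical columns (entity abbreviation, room grade code) are
#' ordinal-encoded against a vocabulary fixed on the training rows; Y/N flags
#' become 1/0; min-max scaling is fitted on training rows only and applied
#' everywhere (no clipping, so out-of-range test values may fall outside
#' `[0, 1]`). The target occupancy rate is left unscaled — it is already a
#' rate in `[0, 1]`, which keeps the sigmoid output head directly
#' interpretable.
#'
#' @param table Daily occupancy table from [aggregate_daily()] or
#'   [occupancy_table()].
#' @param variant `"ward"`, `"room"` or `"room_static"`.
#' @param static_profiles Static profiles (required for `"room_static"`).
#' @param train_range Length-2 date vector `(start, end)` delimiting the rows
#'   used to fit vocabularies and the scaler.
#' @param scaler,vocab Optional pre-fitted scaler/vocabularies (as stored on a
#'   returned dataset) to apply instead of fitting.
#' @return A `model_dataset`: list with `variant`, `data` (encoded
#'   `data.table` with `date`, `entity`, feature columns and `rate`),
#'   `dynamic_cols`, `static_cols`, `scaler`, `vocab`, `train_range`.
#' @export
encode_and_normalize <- function(table, variant = c("ward", "room", "room_static"),
                                 static_profiles = NULL, train_range,
                                 scaler = NULL, vocab = NULL) {
  variant <- match.arg(variant)
  dt <- data.table::as.data.table(table)
  train_range <- as.Date(train_range)
  if (length(train_range) != 2 || train_range[1] > train_range[2])
    stop("train_range must be (start, end) with start <= end", call. = FALSE)
  in_train <- dt$date >= train_range[1] & dt$date <= train_range[2]
  if (!any(in_train))
    stop("train_range contains no rows of the table", call. = FALSE)

  vocab <- vocab %||% list()
  if (is.null(vocab$entity))
    vocab$entity <- sort(unique(dt$entity[in_train]))
  enc <- ordinal_encode(dt$entity, vocab$entity, "entity")
  out <- data.table::data.table(
    date = dt$date, entity = dt$entity, entity_code = enc$code,
    year = dt$year, month = dt$month, week = dt$week, day = dt$day,
    weekday = dt$weekday, holiday = dt$holiday,
    capacity = dt$capacity, occupied = dt$occupied
  )

  static_cols <- NULL
  if (variant == "room_static") {
    if (is.null(static_profiles))
      stop("variant 'room_static' requires static_profiles", call. = FALSE)
    prof <- data.table::as.data.table(static_profiles)
    miss <- setdiff(unique(dt$entity), prof$room)
    if (length(miss))
      stop("static profiles missing for room(s): ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    prof <- prof[match(out$entity, prof$room)]
    if (is.null(vocab$room_code))
      vocab$room_code <- sort(unique(as.character(prof$room_code[in_train])))
    rc <- ordinal_encode(prof$room_code, vocab$room_code, "room code")
    out[, room_code := rc$code]
    for (fl in STATIC_FLAGS) out[, (fl) := yn_to_int(prof[[fl]])]
    static_cols <- c("room_code", STATIC_FLAGS)
  }

  out[, rate := dt$rate]
  dynamic_cols <- c("entity_code", "year", "month", "week", "day", "weekday",
                    "holiday", "capacity", "occupied", "rate")
  scale_cols <- setdiff(c(dynamic_cols, static_cols), "rate")
  if (is.null(scaler)) scaler <- minmax_fit(out[in_train], scale_cols)
  out <- minmax_apply(out, scaler)
  data.table::setorder(out, entity, date)

  structure(
    list(variant = variant, data = out[], dynamic_cols = dynamic_cols,
         static_cols = static_cols, scaler = scaler, vocab = vocab,
         train_range = train_range),
    class = "model_dataset"
  )
}

#' @export
print.model_dataset <- function(x, ...) {
  cat("<model_dataset> variant '", x$variant, "': ", nrow(x$data), " rows, ",
      length(unique(x$data$entity)), " entities, ",
      length(x$dynamic_cols), " dynamic + ",
      length(x$static_cols %||% character()), " static features\n", sep = "")
  invisible(x)
}
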