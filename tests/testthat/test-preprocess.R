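test_that("bed status imputation maps missing to occupied and rejects junk", {
  expect_identical(impute_bed_status(c(NA, "admittable", "discharge")),
                   c(1L, 0L, 0L))
  expect_identical(impute_bed_status(""), 1L)
  expect_error(impute_bed_status(c("admittable", "cleaning")), "cleaning")
})

test_that("date features follow the ISO calendar and the holiday list", {
  f <- derive_date_features("2020-05-27", holidays = korean_holidays())
  expect_equal(f$year, 2020L)
  expect_equal(f$month, 5L)
  expect_equal(f$day, 27L)
  expect_equal(f$weekday, 3L)  # Wednesday
  expect_equal(f$week, 22L)
  expect_equal(f$holiday, 0L)

  g <- derive_date_features(c("2022-08-15", "2022-08-16"),
                            holidays = korean_holidays())
  expect_equal(g$holiday, c(1L, 0L))
  # ranges over a long span
  h <- derive_date_features(seq(as.Date("2020-01-01"), as.Date("2022-12-31"), 1))
  expect_true(all(h$week >= 1 & h$week <= 53))
  expect_true(all(h$weekday >= 1 & h$weekday <= 7))
  expect_true(all(h$month >= 1 & h$month <= 12))
})

test_that("daily aggregation implements the capacity-ratio definition", {
  lay <- tiny_layout()  # W01: rooms of capacity 4 and 2; W02: 3 and 1
  rooms <- names(lay$capacity)
  day <- "2022-03-01"
  # room 1 (capacity 4): 3 beds occupied all 24 h; room 2 (capacity 2): 1 bed
  rec <- data.table::rbindlist(list(
    hand_records(day, "W01", rooms[1], "B1", 24),
    hand_records(day, "W01", rooms[1], "B2", 24),
    hand_records(day, "W01", rooms[1], "B3", 24),
    hand_records(day, "W01", rooms[1], "B4", 0),
    hand_records(day, "W01", rooms[2], "B5", 24),
    hand_records(day, "W01", rooms[2], "B6", 0)
  ))
  tab <- aggregate_daily(rec, lay, "room")
  expect_equal(tab[entity == rooms[1], occupied], 3L)
  expect_equal(tab[entity == rooms[1], rate], 0.75)
  expect_equal(tab[entity == rooms[2], rate], 0.5)

  ward <- aggregate_daily(rec, lay, "ward")
  expect_equal(ward[entity == "W01", occupied], 4L)
  expect_equal(ward[entity == "W01", capacity], 6L)
  expect_equal(ward[entity == "W01", rate], 4 / 6)
})

test_that("partial-day occupancy is the daily mean rounded half-up", {
  lay <- build_layout(1, 1, 1, seed = 1)
  room <- names(lay$capacity)
  tab12 <- aggregate_daily(hand_records("2022-03-01", "W01", room, "B1", 12),
                           lay, "room")
  expect_equal(tab12$occupied, 1L)   # 12/24 = 0.5 rounds up
  tab11 <- aggregate_daily(hand_records("2022-03-01", "W01", room, "B1", 11),
                           lay, "room")
  expect_equal(tab11$occupied, 0L)
  # snapshot rule reads a single reference hour instead
  snap <- aggregate_daily(hand_records("2022-03-01", "W01", room, "B1", 1),
                          lay, "room", daily_rule = "snapshot", snapshot_hour = 0)
  expect_equal(snap$occupied, 1L)
})

test_that("aggregation rejects unknown rooms and incomplete days", {
  lay <- tiny_layout()
  room <- names(lay$capacity)[1]
  ghost <- hand_records("2022-03-01", "W09", "W09R01", "B1", 4)
  expect_error(aggregate_daily(ghost, lay, "room"), "W09R01")
  short <- hand_records("2022-03-01", "W01", room, "B1", 4)[1:23]
  expect_error(aggregate_daily(short, lay, "room"), "23 h")
})

test_that("aggregated rates respect bounds, integrality and ward additivity", {
  lay <- build_layout(3, 4, c(1, 5), seed = 14)
  prof <- sample_static_profiles(lay, rep(0, 13), seed = 14)
  d <- simulate_daily_states(lay, prof, tiny_config(mu = 0.3, rho = .4, sigma = .5))
  rooms <- occupancy_table(d, "room")
  wards <- occupancy_table(d, "ward")
  expect_true(all(rooms$rate >= 0 & rooms$rate <= 1))
  expect_true(all(abs(rooms$rate * rooms$capacity - rooms$occupied) < 1e-9))
  wd <- d[, .(occ = sum(occupied)), by = .(date, ward)]
  chk <- merge(wards, wd, by.x = c("date", "entity"), by.y = c("date", "ward"))
  expect_identical(chk$occupied, chk$occ)
})

test_that("encoding maps flags, fits min-max on training rows only, no clipping", {
  lay <- tiny_layout()
  prof <- tiny_profiles(lay)
  # Y/N flag text is accepted and mapped to 1/0
  profYN <- data.table::copy(prof)
  for (fl in STATIC_FLAGS) profYN[[fl]] <- ifelse(prof[[fl]] == 1, "Y", "N")
  d <- simulate_daily_states(lay, prof,
                             tiny_config(mu = 0, sigma = .4, rho = .3,
                                         start = "2022-01-01", end = "2022-03-31"))
  tab <- occupancy_table(d, "room")
  ds <- encode_and_normalize(tab, "room_static", static_profiles = profYN,
                             train_range = c("2022-01-01", "2022-02-28"))
  enc_flags <- as.matrix(ds$data[, STATIC_FLAGS, with = FALSE])
  raw_flags <- as.matrix(prof[match(ds$data$entity, prof$room), STATIC_FLAGS,
                              with = FALSE])
  # min-max over a 0/1 training column is the identity wherever both levels occur
  varying <- apply(raw_flags, 2, function(x) length(unique(x)) > 1)
  expect_equal(enc_flags[, varying], raw_flags[, varying],
               ignore_attr = TRUE)

  # scaled training rows lie in [0, 1]; the target rate is never rescaled
  in_train <- ds$data$date <= as.Date("2022-02-28")
  sc_cols <- names(ds$scaler)
  expect_true(all(as.matrix(ds$data[in_train, sc_cols, with = FALSE]) >= 0 - 1e-12))
  expect_true(all(as.matrix(ds$data[in_train, sc_cols, with = FALSE]) <= 1 + 1e-12))
  expect_equal(ds$data$rate, tab[order(entity, date)]$rate)

  # affine map without clipping: train min 0 / max 10 sends 5 -> 0.5, 12 -> 1.2
  toy <- data.table::data.table(v = c(0, 10, 5, 12))
  sc <- borcast:::minmax_fit(toy[1:2], "v")
  out <- borcast:::minmax_apply(data.table::copy(toy), sc)
  expect_equal(out$v, c(0, 1, 0.5, 1.2))
})

test_that("encoding vocabulary is stable and unseen categories get the reserved code", {
  ds <- small_ward_dataset()
  expect_identical(ds$vocab$entity, sort(ds$vocab$entity))
  # re-encode a table containing an entity absent from the training vocabulary
  lay <- build_layout(3, 4, c(2, 6), seed = 9)
  prof <- sample_static_profiles(lay, rep(0.2, 13), seed = 9)
  cfg <- sim_config("2022-01-01", "2022-01-31", mu = 0, sigma = .2, seed = 1)
  tab <- occupancy_table(simulate_daily_states(lay, prof, cfg), "ward")
  tab[entity == "W01", entity := "W99"]
  msgs <- capture_messages(
    ds2 <- encode_and_normalize(tab, "ward",
                                train_range = c("2022-01-01", "2022-01-31"),
                                vocab = list(entity = c("W02", "W03")))
  )
  expect_true(any(grepl("reserved code 0", msgs)))
  # W99's reserved raw code 0 is the training minimum, so it scales to 0
  # while the in-vocabulary entities scale strictly above it
  expect_true(all(ds2$data[entity == "W99", entity_code] == 0))
  expect_true(all(ds2$data[entity != "W99", entity_code] > 0))
})

test_that("min-max scaling is idempotent once data are in scaler coordinates", {
  set.seed(4)
  toy <- data.table::data.table(a = runif(50, -3, 7), b = rnorm(50))
  sc <- borcast:::minmax_fit(toy, c("a", "b"))
  once <- borcast:::minmax_apply(data.table::copy(toy), sc)
  # refitting on scaled data yields the identity scaler (min 0, range 1)
  sc2 <- borcast:::minmax_fit(once, c("a", "b"))
  twice <- borcast:::minmax_apply(data.table::copy(once), sc2)
  expect_equal(twice, once)
  # and inversion recovers the original values
  back <- borcast:::minmax_invert(data.table::copy(once), sc)
  expect_equal(back$a, toy$a)
  expect_equal(back$b, toy$b)
})
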