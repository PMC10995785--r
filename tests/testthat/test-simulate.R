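test_that("build_layout satisfies the hierarchy invariants and is deterministic", {
  lay <- build_layout(1, 1, 4, seed = 3)
  expect_equal(unname(ward_capacity(lay)), 4L)

  lay2 <- build_layout(2, 3, 2, seed = 3)
  expect_equal(sum(lay2$capacity), 12L)
  expect_equal(length(lay2$wards), 2L)
  # every room belongs to exactly one ward; ward capacity adds up
  expect_setequal(unlist(lay2$rooms), names(lay2$capacity))
  expect_equal(sum(ward_capacity(lay2)), sum(lay2$capacity))

  a <- build_layout(4, c(1, 5), c(1, 8), seed = 77)
  b <- build_layout(4, c(1, 5), c(1, 8), seed = 77)
  expect_identical(a, b)
  expect_true(all(a$capacity >= 1))

  expect_error(build_layout(0, 1, 1), "n_wards")
  expect_error(build_layout(2, 0, 1), ">= 1")
})

test_that("static profiles are Bernoulli draws with the requested rates", {
  lay <- build_layout(1, 2000, 1, seed = 1)
  p0 <- sample_static_profiles(lay, rep(0, 13), seed = 2)
  expect_true(all(as.matrix(p0[, STATIC_FLAGS, with = FALSE]) == 0))
  p1 <- sample_static_profiles(lay, rep(1, 13), seed = 2)
  expect_true(all(as.matrix(p1[, STATIC_FLAGS, with = FALSE]) == 1))

  # per-flag sample means inside the exact binomial 99% interval around 0.3
  p3 <- sample_static_profiles(lay, rep(0.3, 13), seed = 8)
  ci <- binom99(2000, 0.3)
  means <- colMeans(as.matrix(p3[, STATIC_FLAGS, with = FALSE]))
  expect_true(all(means >= ci[1] & means <= ci[2]))

  expect_equal(nrow(p3), 2000L)
  expect_error(sample_static_profiles(lay, rep(1.2, 13)), "\\[0, 1\\]")
})

test_that("daily occupancy follows the latent-logit model in its limits", {
  lay <- tiny_layout()
  prof <- tiny_profiles(lay)

  # saturated logit: every bed occupied every day
  full <- simulate_daily_states(lay, prof, tiny_config(mu = 50))
  expect_true(all(full$occupied == full$capacity))

  # strongly negative holiday effect empties the hospital on the holiday
  hol <- as.Date("2022-03-15")
  empty_hol <- simulate_daily_states(
    lay, prof, tiny_config(mu = 2, beta_holiday = -100, holidays = hol))
  expect_true(all(empty_hol[date == hol, occupied] == 0))
  expect_gt(mean(empty_hol[date != hol, occupied]), 0)

  # counts always within [0, capacity]
  noisy <- simulate_daily_states(
    lay, prof, tiny_config(mu = 0, rho = 0.8, sigma = 1))
  expect_true(all(noisy$occupied >= 0 & noisy$occupied <= noisy$capacity))
})

test_that("neutral simulation is centred on one-half occupancy", {
  lay <- build_layout(5, 10, 4, seed = 2)   # 50 rooms x 4 beds
  prof <- sample_static_profiles(lay, rep(0, 13), seed = 2)
  cfg <- tiny_config(mu = 0, start = "2022-01-01", end = "2022-02-19", seed = 6)
  daily <- simulate_daily_states(lay, prof, cfg)
  ci <- binom99(sum(daily$capacity), 0.5)
  pooled <- sum(daily$occupied) / sum(daily$capacity)
  expect_gte(pooled, ci[1])
  expect_lte(pooled, ci[2])
})

test_that("expected occupancy is monotone in the base logit", {
  # sigma = 0 and large capacities: per-room mean rates estimate plogis(z)
  # with sd ~ 0.004, so monotonicity in mu must hold far beyond that noise
  lay <- build_layout(2, 5, 200, seed = 4)
  prof <- sample_static_profiles(lay, rep(0, 13), seed = 4)
  mus <- c(-2, -1, 0, 1, 2)
  rates <- sapply(mus, function(mu) {
    d <- simulate_daily_states(
      lay, prof, tiny_config(mu = mu, start = "2022-01-01", end = "2022-03-01",
                             seed = 9))
    d[, sum(occupied) / sum(capacity), by = room]$V1
  })
  expect_true(all(t(apply(rates, 1, diff)) > 0.02))
})

test_that("positive holiday effect raises holiday occupancy", {
  lay <- build_layout(4, 10, 3, seed = 5)   # 40 rooms -> >= 1000 room-days per group
  prof <- sample_static_profiles(lay, rep(0, 13), seed = 5)
  hol <- seq(as.Date("2022-01-02"), as.Date("2022-03-31"), by = "2 days")
  cfg <- tiny_config(mu = -0.5, beta_holiday = 1.5, holidays = hol,
                     start = "2022-01-01", end = "2022-03-31", seed = 12)
  d <- simulate_daily_states(lay, prof, cfg)
  d[, is_hol := date %in% hol]
  grp <- d[, .(rate = sum(occupied) / sum(capacity), n = .N), by = is_hol]
  expect_true(all(grp$n >= 1000))
  expect_gt(grp[is_hol == TRUE, rate], grp[is_hol == FALSE, rate])
})

test_that("simulation and hourly expansion are deterministic given the config", {
  lay <- tiny_layout()
  prof <- tiny_profiles(lay)
  cfg <- tiny_config(mu = 0.2, rho = 0.5, sigma = 0.4)
  d1 <- simulate_daily_states(lay, prof, cfg)
  d2 <- simulate_daily_states(lay, prof, cfg)
  expect_identical(d1, d2)
  expect_identical(expand_to_hourly(d1, lay), expand_to_hourly(d2, lay))
})

test_that("hourly expansion emits 24 records per bed-day with day-constant status", {
  lay <- build_layout(1, 1, 2, seed = 1)  # 2 beds
  prof <- sample_static_profiles(lay, rep(0, 13), seed = 1)
  cfg <- tiny_config(mu = 0, sigma = 0.5, start = "2022-03-01", end = "2022-03-02")
  d <- simulate_daily_states(lay, prof, cfg)
  rec <- expand_to_hourly(d, lay)
  expect_equal(nrow(rec), 2 * 2 * 24)

  # a full room-day has no admittable/discharge records
  lay4 <- tiny_layout()
  full <- simulate_daily_states(lay4, tiny_profiles(lay4), tiny_config(mu = 50))
  rec_full <- expand_to_hourly(full, lay4)
  expect_true(all(is.na(rec_full$status)))
})

test_that("re-aggregating the hourly stream recovers the daily states exactly", {
  lay <- build_layout(3, 5, c(1, 5), seed = 21)
  prof <- sample_static_profiles(lay, rep(0.2, 13), seed = 21)
  cfg <- tiny_config(mu = 0.1, beta_dow = c(.3, .2, .1, 0, -.1, -.4, -.5),
                     rho = 0.5, sigma = 0.4, seed = 33)
  daily <- simulate_daily_states(lay, prof, cfg)
  rec <- expand_to_hourly(daily, lay)
  tab <- aggregate_daily(rec, lay, "room")
  merged <- merge(daily, tab[, .(date, room = entity, occ2 = occupied)],
                  by = c("date", "room"))
  expect_equal(nrow(merged), nrow(daily))
  expect_identical(merged$occupied, merged$occ2)
})

test_that("record CSV writer round-trips including the missing-status encoding", {
  lay <- tiny_layout()
  d <- simulate_daily_states(lay, tiny_profiles(lay),
                             tiny_config(mu = 0, sigma = 0.5,
                                         start = "2022-03-01", end = "2022-03-03"))
  rec <- expand_to_hourly(d, lay)
  f <- tempfile(fileext = ".csv")
  write_bed_records(rec, f)
  expect_true(any(is.na(rec$status)))
  back <- read_bed_records(f)
  expect_equal(as.data.frame(back), as.data.frame(rec))
  unlink(f)

  prof <- tiny_profiles(lay)
  f2 <- tempfile(fileext = ".csv")
  write_static_profiles(prof, f2)
  expect_equal(as.data.frame(read_static_profiles(f2)), as.data.frame(prof))
  unlink(f2)
})

test_that("the packaged holiday calendar has 27 days inside the study window", {
  hol <- korean_holidays()
  expect_length(hol, 27)
  expect_true(all(hol >= as.Date("2020-05-27") & hol <= as.Date("2022-11-21")))
  expect_false(is.unsorted(hol))
})
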