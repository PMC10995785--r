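test_that("metrics match hand-computed worked examples", {
  # perfect prediction
  m <- compute_metrics(c(0.2, 0.4, 0.9), c(0.2, 0.4, 0.9))
  expect_equal(unlist(m[c("mae", "mse", "rmse", "r2")]),
               c(mae = 0, mse = 0, rmse = 0, r2 = 1))

  # y = (0,1), yhat = (1,0): SSR = 2, SST = 0.5 -> R2 = -3
  m <- compute_metrics(c(0, 1), c(1, 0))
  expect_equal(m$mae, 1)
  expect_equal(m$mse, 1)
  expect_equal(m$rmse, 1)
  expect_equal(m$r2, -3)

  # SSR = 0.03, SST = 0.08 -> R2 = 0.625
  m <- compute_metrics(c(0.2, 0.4, 0.6), c(0.3, 0.5, 0.5))
  expect_equal(m$mae, 0.1)
  expect_equal(m$mse, 0.01)
  expect_equal(m$rmse, 0.1)
  expect_equal(m$r2, 0.625)

  expect_error(compute_metrics(1:3, 1:2), "equal length")
  expect_warning(m0 <- compute_metrics(c(0.5, 0.5), c(0.4, 0.6)), "SST")
  expect_true(is.na(m0$r2))
})

test_that("metrics agree with a brute-force reference on random pairs", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(2:40, 1)
    y <- runif(n); p <- runif(n)
    a <- compute_metrics(y, p)
    b <- ref_metrics(y, p)
    expect_equal(a$mae, b$mae, tolerance = 1e-12)
    expect_equal(a$mse, b$mse, tolerance = 1e-12)
    expect_equal(a$rmse, b$rmse, tolerance = 1e-12)
    expect_equal(a$r2, b$r2, tolerance = 1e-12)
    expect_equal(a$rmse^2, a$mse, tolerance = 1e-12)
    expect_lte(a$mae, a$rmse + 1e-12)
  }
})

test_that("error metrics are shift-invariant and R2 is affine-invariant", {
  set.seed(5)
  y <- runif(30); p <- runif(30)
  a <- compute_metrics(y, p)
  sh <- compute_metrics(y + 2.5, p + 2.5)
  expect_equal(sh$mae, a$mae)
  expect_equal(sh$mse, a$mse)
  expect_equal(sh$rmse, a$rmse)
  expect_equal(sh$r2, a$r2)
  af <- compute_metrics(-3 * y + 1, -3 * p + 1)
  expect_equal(af$r2, a$r2)
})

test_that("fold summary reproduces printed mean cells and validates shape", {
  reports <- data.table::data.table(
    model = "bilstm_W7D", fold = 1:5,
    mae = c(0.063, 0.054, 0.091, 0.068, 0.060),
    mse = c(0.007, 0.005, 0.016, 0.009, 0.007),
    rmse = c(0.086, 0.071, 0.126, 0.098, 0.087),
    r2 = c(0.479, 0.606, 0.408, 0.537, 0.690)
  )
  s <- fold_summary(reports)
  expect_equal(nrow(s), 6L)
  mean_row <- s[fold == "Mean"]
  expect_equal(mean_row$mae, 0.067)
  expect_equal(mean_row$r2, 0.544)
  # constant folds: the mean is that constant
  const <- data.table::data.table(model = "m", fold = 1:3, mae = 0.2,
                                  mse = 0.04, rmse = 0.2, r2 = 0.5)
  expect_equal(fold_summary(const)[fold == "Mean", mae], 0.2)
  # ragged fold counts are rejected
  ragged <- rbind(reports, const)
  expect_error(fold_summary(ragged), "ragged")
})

test_that("split proportions are half-up percentages to one decimal", {
  expect_equal(split_proportions(c(1, 1)), c(50.0, 50.0))
  expect_equal(split_proportions(c(3, 1)), c(75.0, 25.0))
  expect_equal(sum(split_proportions(c(1, 1, 1))), 100, tolerance = 0.11)
  expect_error(split_proportions(c(0, 0)), "zero")
  expect_error(split_proportions(c(-1, 2)), "nonnegative")
})

test_that("rounding is half away from zero at the printed precision", {
  expect_equal(round_half_up(0.0005, 3), 0.001)
  expect_equal(round_half_up(0.0675, 3), 0.068)
  expect_equal(round_half_up(-0.0685, 3), -0.069)
  expect_equal(round_half_up(67.75, 1), 67.8)
})

make_pred_df <- function() {
  data.table::data.table(
    entity = rep(c("W01", "W02"), each = 20),
    target_date = rep(as.Date("2022-07-01") + 0:19, 2),
    y_true = runif(40, 0.3, 0.9), y_pred = runif(40, 0.3, 0.9)
  )
}

test_that("predicted-vs-actual plot validates inputs and writes a file", {
  set.seed(2)
  pr <- make_pred_df()
  expect_error(plot_predicted_vs_actual(pr, "W99", "2022-07-01", "2022-07-10"),
               "available")
  expect_error(plot_predicted_vs_actual(pr, "W01", "2023-01-01", "2023-02-01"),
               "no predictions")
  p <- plot_predicted_vs_actual(pr, "W01", "2022-07-01", "2022-07-10")
  expect_s3_class(p, "ggplot")
  expect_equal(nrow(p$data), 2 * 10)  # actual + predicted curve per date
  f <- tempfile(fileext = ".png")
  plot_predicted_vs_actual(pr, "W01", "2022-07-01", "2022-07-10", file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  unlink(f)
})

test_that("dashboard feed balances beds and round-trips through JSON", {
  set.seed(3)
  tab <- data.table::data.table(
    date = as.Date("2022-07-10"), entity = c("W01", "W02"), level = "ward",
    capacity = c(6L, 10L), occupied = c(3L, 9L), rate = c(0.5, 0.9)
  )
  pr <- data.table::data.table(entity = c("W01", "W02"),
                               target_date = as.Date("2022-07-11"),
                               y_true = c(0.5, 0.8), y_pred = c(0.55, 0.85))
  feed <- export_dashboard_feed(pr, tab, "2022-07-10")
  w1 <- feed$wards[[1]]
  expect_equal(w1$free, 3L)
  expect_equal(w1$occupied + w1$free, w1$capacity)
  expect_equal(w1$rate, 0.5)
  expect_equal(w1$predicted_rate_next_day, 0.55)
  # hospital rate is the capacity-weighted ward aggregate
  expect_equal(feed$hospital$rate, 12 / 16)
  expect_equal(feed$hospital$rate,
               sum(tab$rate * tab$capacity) / sum(tab$capacity))
  f <- tempfile(fileext = ".json")
  export_dashboard_feed(pr, tab, "2022-07-10", file = f)
  back <- read_dashboard_feed(f)
  expect_equal(back$hospital$capacity, 16L)
  expect_equal(back$wards[[2]]$predicted_rate_next_day, 0.85)
  expect_equal(back$as_of, "2022-07-10")
  unlink(f)
  expect_error(export_dashboard_feed(pr, tab, "2022-07-11"), "not covered")
})
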