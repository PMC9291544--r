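test_that("the percentile threshold uses linear interpolation on the baseline", {
  expect_equal(unname(mhw_threshold(1:100, probs = 90)), 90.1)
  # constant baseline: threshold equals the constant for any percentile
  expect_equal(unname(mhw_threshold(rep(27, 50), probs = 99)), 27)
  # higher percentile never yields a lower threshold
  set.seed(2)
  x <- rnorm(500, 27, 1)
  thr <- mhw_threshold(x, probs = c(90, 99))
  expect_gte(thr[["p99"]], thr[["p90"]])
  expect_error(mhw_threshold(numeric(0)), "empty baseline")
  # baseline can be restricted by a date range
  dates <- as.Date("2000-01-01") + 0:99
  thr2 <- mhw_threshold(c(1:50, rep(100, 50)), dates = dates,
                        baseline = as.Date(c("2000-01-01", "2000-02-19")),
                        probs = 90)
  expect_equal(unname(thr2), quantile(1:50, 0.9, type = 7, names = FALSE))
})

test_that("event detection finds maximal exceedance runs without gap-joining", {
  sst <- rep(27, 60)
  expect_equal(nrow(mhw_events(1:60, sst, 28)), 0)

  sst[20:24] <- 28.5  # one 5-day excursion to threshold + 0.5
  ev <- mhw_events(1:60, sst, 28)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_days, 5)
  expect_equal(ev$max_intensity_C, 0.5)
  expect_equal(ev$start, 20)
  expect_equal(ev$end, 24)

  # two excursions separated by one sub-threshold day stay separate events
  sst2 <- rep(27, 30)
  sst2[10:12] <- 29
  sst2[14:16] <- 29
  ev2 <- mhw_events(1:30, sst2, 28, min_duration = 1)
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$duration_days, c(3, 3))
  # a 5-day minimum removes both short runs
  expect_equal(nrow(mhw_events(1:30, sst2, 28, min_duration = 5)), 0)

  expect_error(mhw_events(c(1, 1, 2), rep(29, 3), 28), "strictly increasing")
})

test_that("annual statistics attribute events and days to calendar years", {
  # 365-day calendar via integer day indices; two years
  sst <- rep(27, 730)
  sst[100:109] <- 28  # 10-day event at +1 in year 1
  sst[360:370] <- 28.5  # 11-day event crossing the year boundary
  ann <- mhw_annual_stats(1:730, sst, 27.5)
  expect_equal(ann$year, c(1, 2))
  # event stats go to the start year, day counts to each constituent day
  expect_equal(ann$mean_annual_duration_days, c((10 + 11) / 2, NA))
  expect_equal(ann$max_annual_intensity_C, c(1, NA))
  expect_equal(ann$n_mhw_days, c(10 + 6, 5))

  # a year without events yields zero days and missing intensity
  quiet <- mhw_annual_stats(1:365, rep(27, 365), 28)
  expect_equal(quiet$n_mhw_days, 0)
  expect_true(is.na(quiet$max_annual_intensity_C))

  # with min_duration = 1 and no boundary crossing, total event days equal
  # the sum of event durations
  set.seed(4)
  noisy <- 27 + rnorm(365)
  ev <- mhw_events(1:365, noisy, 28)
  ann2 <- mhw_annual_stats(1:365, noisy, 28, events = ev)
  expect_equal(ann2$n_mhw_days, sum(ev$duration_days))
})

test_that("the multi-model envelope reduces to mean, min and max per year", {
  a <- data.frame(year = 1:3, max_annual_intensity_C = c(1.0, 1.2, 1.1),
                  mean_annual_duration_days = c(10, 12, 11), n_mhw_days = c(20, 25, 22))
  b <- transform(a, max_annual_intensity_C = max_annual_intensity_C + 0.4,
                 mean_annual_duration_days = mean_annual_duration_days + 2,
                 n_mhw_days = n_mhw_days + 5)
  env <- mhw_envelope(list(m1 = a, m2 = b))
  expect_equal(env$max_annual_intensity_C_mean[1], 1.2)
  expect_equal(env$max_annual_intensity_C_min, a$max_annual_intensity_C)
  expect_equal(env$max_annual_intensity_C_max, b$max_annual_intensity_C)
  # constant offset -> constant envelope width
  expect_equal(env$n_mhw_days_max - env$n_mhw_days_min, rep(5, 3))
  # one model: mean = min = max
  solo <- mhw_envelope(list(only = a))
  expect_equal(solo$n_mhw_days_mean, a$n_mhw_days)
  expect_equal(solo$n_mhw_days_min, solo$n_mhw_days_max)
})

test_that("day-of-year climatology mode returns per-day thresholds", {
  s <- sim_sst(years = 4, baseline_years = 4, seasonal_amplitude_C = 3,
               noise_sd_C = 0, ar1 = 0)
  thr <- mhw_threshold(s$data$sst, dates = s$data$date,
                       baseline = s$baseline, probs = 90,
                       climatology = TRUE)
  expect_equal(nrow(thr), nrow(s$data))
  # the seasonal cycle is absorbed by the climatology: per-day thresholds
  # track the sine, so no day exceeds its own climatology by much
  expect_lt(max(s$data$sst - thr[, 1]), 0.5)
  # whereas the pooled threshold is exceeded by the top of the seasonal
  # cycle on about 10% of days
  pooled <- mhw_threshold(s$data$sst, baseline = s$baseline, probs = 90)
  expect_equal(mean(s$data$sst > pooled), 0.1, tolerance = 0.02)
})

test_that("SST CSV reader accepts dates and model ids", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(date = as.character(as.Date("1900-01-01") + 0:9),
                   sst = 27 + (0:9) / 10, model_id = "CanESM2")
  write.csv(df, path, row.names = FALSE)
  got <- read_sst(path)
  expect_s3_class(got$date, "Date")
  expect_equal(got$model_id[1], "CanESM2")
})
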