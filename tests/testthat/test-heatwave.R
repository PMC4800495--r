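test_that("constant base series gives constant thresholds and no events", {
  th <- calendar_thresholds(rep(20, 365 * 30))
  expect_length(as.numeric(th), 365)
  expect_true(all(th == 20))
  ev <- detect_events(rep(20, 365 * 5), th)
  expect_equal(nrow(ev), 0)  # strict exceedance: ties do not count
})

test_that("thresholds match the brute-force pooled percentile oracle", {
  set.seed(5)
  series <- 15 + 10 * cos(2 * pi * (rep(1:365, 30) - 196) / 365) +
    rnorm(365 * 30, 0, 3)
  th <- calendar_thresholds(series, percentile = 0.9, window_halfwidth = 7)
  expect_equal(as.numeric(th), oracle_thresholds(series, 0.9, 7),
               tolerance = 1e-12)
  # pooled sample size 30 x 15 = 450: reproduce one day fully by hand
  pool <- c()
  for (k in -7:7) {
    dd <- ((200 + k - 1) %% 365) + 1
    pool <- c(pool, series[dd + 365 * (0:29)])
  }
  expect_length(pool, 450)
  expect_equal(as.numeric(th)[200], oracle_quantile(pool, 0.9),
               tolerance = 1e-12)
})

test_that("trend within the base period raises mid-summer thresholds", {
  doy <- rep(1:365, 30)
  series <- 10 + 12 * cos(2 * pi * (doy - 196) / 365) +
    0.05 * seq_along(doy) / 365
  th <- as.numeric(calendar_thresholds(series))
  expect_gt(mean(th[182:212]), mean(th[c(60:90, 274:304)]))
})

test_that("run-length pattern [2,3,1,4] yields events of 3 and 4 days", {
  th <- rep(20, 365)
  x <- rep(10, 365)
  x[11:12] <- 25           # run of 2: discarded
  x[21:23] <- 25           # run of 3: event
  x[31] <- 25              # run of 1: discarded
  x[41:44] <- 25           # run of 4: event
  ev <- detect_events(x, th)
  expect_equal(ev$start_day, c(21, 41))
  expect_equal(ev$duration, c(3, 4))
  expect_equal(nrow(ev), 2)
  expect_equal(mean(ev$duration), 3.5)
})

test_that("event sets match an independent brute-force scanner", {
  set.seed(99)
  th_series <- rnorm(365 * 30, 18, 4)
  th <- calendar_thresholds(th_series)
  for (r in 1:50) {  # the 1000-series sweep runs in the acceptance suite
    x <- rnorm(365 * 2, 18, 5)
    ev <- detect_events(x, th)
    or <- oracle_events(x, as.numeric(th))
    expect_equal(ev$start_day, or$start_day)
    expect_equal(ev$duration, or$duration)
  }
})

test_that("event days are disjoint and cover exactly the qualifying runs", {
  set.seed(13)
  x <- rnorm(365 * 3, 20, 6)
  th <- rep(22, 365)
  ev <- detect_events(x, th)
  days <- unlist(mapply(function(s, d) s:(s + d - 1), ev$start_day,
                        ev$duration, SIMPLIFY = FALSE))
  expect_equal(anyDuplicated(days), 0)
  exceed <- x > th[((seq_along(x) - 1) %% 365) + 1]
  r <- rle(exceed)
  runs <- sum(r$lengths[r$values & r$lengths >= 3])
  expect_length(days, runs)
  expect_true(all(exceed[days]))
})

test_that("summary indices follow their definitions", {
  th <- rep(28, 365)
  x <- rep(20, 365)
  x[180:182] <- c(31, 32, 33)
  ev <- detect_events(x, th)
  s <- heatwave_summary(x, ev)
  expect_equal(s$hw_frequency, 1)
  expect_equal(s$hw_duration, 3)
  expect_equal(s$hw_intensity, 32)
  expect_equal(s$hw_max_intensity, 33)
  expect_equal(s$txx, 33)

  # two events, pooled event-day mean vs per-event means
  y <- rep(20, 365)
  y[170:172] <- 30; y[200:202] <- 34
  evy <- detect_events(y, th)
  sp <- heatwave_summary(y, evy)
  expect_equal(sp$hw_frequency, 2)
  expect_equal(sp$hw_intensity, 32)  # pooled over 6 event days
  se <- heatwave_summary(y, evy, intensity = "event_mean")
  expect_equal(se$hw_intensity, mean(c(30, 34)))

  # txx is the plain yearly maximum
  z <- rep(10, 365); z[50] <- 38.2
  expect_equal(heatwave_summary(z, detect_events(z, th))$txx, 38.2)
})

test_that("no-event summers report frequency 0 and missing intensity", {
  x <- rep(15, 365 * 2); x[565:567] <- 40  # JJA event in year 2 only
  th <- rep(20, 365)
  s <- heatwave_summary(x, detect_events(x, th))
  expect_equal(s$hw_frequency, c(0, 1))
  expect_true(is.na(s$hw_duration[1]) && is.na(s$hw_intensity[1]))
  expect_false(is.na(s$hw_intensity[2]))
})

test_that("events are attributed to the season of their start day", {
  th <- rep(20, 365)
  x <- rep(10, 365)
  x[150:154] <- 25  # starts day 150, before JJA (152)
  s <- heatwave_summary(x, detect_events(x, th))
  expect_equal(s$hw_frequency, 0)
  x2 <- rep(10, 365)
  x2[242:246] <- 25  # starts inside JJA, ends after
  s2 <- heatwave_summary(x2, detect_events(x2, th))
  expect_equal(s2$hw_frequency, 1)
})

test_that("raising the percentile never lowers any threshold", {
  set.seed(3)
  series <- rnorm(365 * 30, 15, 5)
  t90 <- as.numeric(calendar_thresholds(series, percentile = 0.90))
  t95 <- as.numeric(calendar_thresholds(series, percentile = 0.95))
  expect_true(all(t95 >= t90))
})

test_that("uniform warming shifts intensity but not frequency or duration", {
  set.seed(8)
  base <- 15 + 10 * cos(2 * pi * (rep(1:365, 32) - 196) / 365) +
    rnorm(365 * 32, 0, 3)
  delta <- 2.5
  th_a <- calendar_thresholds(base[1:(365 * 30)])
  th_b <- calendar_thresholds(base[1:(365 * 30)] + delta)
  expect_equal(as.numeric(th_b), as.numeric(th_a) + delta,
               tolerance = 1e-12)
  sa <- heatwave_summary(base, detect_events(base, th_a))
  sb <- heatwave_summary(base + delta, detect_events(base + delta, th_b))
  expect_equal(sb$hw_frequency, sa$hw_frequency)
  expect_equal(sb$hw_duration, sa$hw_duration)
  expect_equal(sb$hw_intensity, sa$hw_intensity + delta, tolerance = 1e-12)
  expect_equal(sb$txx, sa$txx + delta, tolerance = 1e-12)
})

test_that("pdf_summary normalises to 100% and shifts bin-exactly", {
  expect_equal(sum(pdf_summary(rnorm(500), 0.25)$pct), 100,
               tolerance = 1e-9)
  one <- pdf_summary(3.2, 0.5)
  expect_equal(one$pct[one$pct > 0], 100)
  x <- rnorm(400, 20, 3)
  a <- pdf_summary(x, 0.5)
  b <- pdf_summary(x + 2, 0.5)  # shift by 4 bins
  common_a <- a$pct[a$pct > 0]
  common_b <- b$pct[b$pct > 0]
  expect_equal(common_a, common_b)
  expect_equal(b$mid[b$pct > 0], a$mid[a$pct > 0] + 2)
})

test_that("threshold computation rejects gappy or ragged input", {
  expect_error(calendar_thresholds(c(rep(20, 400))), "multiple of 365")
  x <- rep(20, 365 * 2); x[5] <- NA
  expect_error(calendar_thresholds(x), "gap-free")
})
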