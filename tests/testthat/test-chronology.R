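# RWL I/O, spline detrending, prewhitening, biweight means, chronologies.

test_that("RWL files round-trip and the terminator declares the units", {
  rs <- ring_series("TREE01", 1994, c(1.23, 0.98, 1.57), latitude = 62)
  path <- withr::local_tempfile(fileext = ".rwl")
  write_rwl(rs, path, precision = 0.01)
  back <- read_rwl(path)
  expect_length(back, 1L)
  expect_equal(back[[1]]$id, "TREE01")
  expect_equal(back[[1]]$first_year, 1994L)
  expect_equal(back[[1]]$values, c(1.23, 0.98, 1.57))
  # -9999 terminator means 0.001 mm units
  write_rwl(ring_series("T2", 2000, c(1.234, 0.456)), path, precision = 0.001)
  expect_equal(read_rwl(path)[[1]]$values, c(1.234, 0.456))
  # a multi-decade, multi-series file
  set.seed(4)
  many <- list(ring_series("AAA", 1987, runif(40, 0.5, 3)),
               ring_series("BBB", 1990, runif(25, 0.5, 3)))
  write_rwl(many, path)
  back <- read_rwl(path)
  expect_equal(vapply(back, function(s) s$id, ""), c("AAA", "BBB"))
  expect_equal(back[[1]]$values, round(many[[1]]$values, 2))
  expect_equal(back[[2]]$first_year, 1990L)
})

test_that("read_rwl reports malformed files by series id", {
  path <- withr::local_tempfile(fileext = ".rwl")
  writeLines("BAD     1990   123   456", path) # no terminator
  expect_error(read_rwl(path), "BAD.*terminator")
  writeLines(c("XYZ     1990   123   456", "XYZ     1980   111   999"), path)
  expect_error(read_rwl(path), "non-monotone.*XYZ")
})

test_that("detrending a constant series gives indices of exactly 1", {
  rs <- ring_series("CONST", 1900, rep(1.5, 80))
  idx <- spline_detrend(rs)
  expect_equal(idx$values, rep(1, 80), tolerance = 1e-10)
  expect_error(spline_detrend(ring_series("SHORT", 1900, rep(1, 5))),
               "too short")
})

test_that("spline amplitude response is 50% at the cutoff wavelength", {
  n <- 600
  t <- seq_len(n)
  amp <- 0.15
  # retained amplitude ~0.5 at the 60-yr cutoff wavelength...
  rs60 <- ring_series("S60", 1, 1 + amp * sin(2 * pi * t / 60))
  idx <- spline_detrend(rs60, cutoff_years = 60)
  a60 <- sinusoid_amplitude(t, idx$values, 60)
  expect_gt(a60, (0.5 - 0.1) * amp)
  expect_lt(a60, (0.5 + 0.1) * amp)
  # ...while a 6-yr (high-frequency) signal passes nearly untouched
  rs6 <- ring_series("S6", 1, 1 + amp * sin(2 * pi * t / 6))
  a6 <- sinusoid_amplitude(t, spline_detrend(rs6, 60)$values, 6)
  expect_gt(a6, 0.9 * amp)
})

test_that("retained amplitude decreases monotonically with wavelength", {
  n <- 800
  t <- seq_len(n)
  kept <- vapply(c(6, 20, 60, 200), function(wl) {
    rs <- ring_series("W", 1, 1 + 0.1 * sin(2 * pi * t / wl))
    sinusoid_amplitude(t, spline_detrend(rs, 60)$values, wl)
  }, 1)
  expect_true(all(diff(kept) < 0))
})

test_that("detrended indices have mean near 1", {
  set.seed(21)
  for (i in 1:5) {
    n <- sample(50:200, 1)
    vals <- 2 * exp(-(1:n) / 120) * exp(rnorm(n, 0, 0.2))
    idx <- spline_detrend(ring_series("R", 1900, vals))
    expect_lt(abs(mean(idx$values) - 1), 0.02)
  }
})

test_that("AR(1) prewhitening removes lag-1 persistence", {
  lag1 <- function(x) cor(x[-1], x[-length(x)])
  n <- 500
  # white noise in, roughly the same out
  wn <- annual_series(1:n, withr::with_seed(7, rnorm(n, 1, 0.1)), name = "wn")
  out <- prewhiten_ar1(wn)
  expect_lt(abs(lag1(out$values)), 2 / sqrt(n))
  expect_gt(cor(out$values, wn$values[-1]), 0.95)
  # strongly autocorrelated in, white out, level retained
  ar <- withr::with_seed(8, as.numeric(arima.sim(list(ar = 0.6), n))) * 0.1 + 1
  out2 <- prewhiten_ar1(annual_series(1:n, ar, name = "ar"))
  expect_lt(abs(lag1(out2$values)), 2 / sqrt(n))
  expect_equal(mean(out2$values), mean(ar), tolerance = 0.02)
  expect_error(prewhiten_ar1(annual_series(1:20, rep(1, 20))), "zero variance")
})

test_that("biweight mean matches an independent reference implementation", {
  expect_equal(biweight_mean(c(5, 5, 5)), 5)
  expect_equal(biweight_mean(c(1, 2, 3)), 2)
  # a gross outlier is downweighted to (almost) nothing
  bw <- biweight_mean(c(1, 2, 3, 100))
  expect_equal(bw, 2, tolerance = 1e-6)
  expect_lt(abs(bw - 2), abs(mean(c(1, 2, 3, 100)) - 2))
  # frozen value from an independent implementation of the same estimator
  x <- c(10.164989, 9.071163, 10.10103, 11.372462, 6.486419, 13.368863,
         9.084314, 8.80716, 7.906065, 11.863584, 11.349961, 12.488882,
         11.786175, 10.52601, 10.657036)
  expect_equal(biweight_mean(x), 10.369244562456396, tolerance = 1e-6)
  # robustness: a wild point barely moves the estimate
  expect_equal(biweight_mean(c(x, 1000)), 10.366191699656051, tolerance = 1e-6)
  # cross-check on random configurations
  set.seed(33)
  for (i in 1:20) {
    z <- rnorm(sample(3:40, 1), sd = sample(c(0.1, 1, 10), 1))
    expect_equal(biweight_mean(z), ref_biweight(z), tolerance = 1e-8)
    expect_gte(biweight_mean(z), min(z))
    expect_lte(biweight_mean(z), max(z))
  }
  expect_error(biweight_mean(numeric(0)), ">= 1")
})

test_that("chronologies recover a shared multiplicative signal", {
  set.seed(55)
  n <- 120
  signal <- exp(0.15 * rnorm(n))
  series <- lapply(1:20, function(i) {
    noise <- exp(rnorm(n, 0, 0.1))
    ring_series(sprintf("T%02d", i), 1901,
                2 * exp(-(1:n) / 150) * signal * noise, latitude = 65)
  })
  ch <- build_chronology(series, min_depth = 1, prewhiten = FALSE)
  expect_gt(cor(ch$index$values, signal), 0.9)
  # single series, min_depth 1: chronology = its index series
  one <- build_chronology(series[1], min_depth = 1, prewhiten = TRUE)
  direct <- prewhiten_ar1(spline_detrend(series[[1]]))
  expect_equal(one$index$values, direct$values, tolerance = 1e-12)
  # order invariance
  ch2 <- build_chronology(rev(series), min_depth = 1, prewhiten = FALSE)
  expect_equal(ch2$index$values, ch$index$values)
})

test_that("min_depth removes thinly replicated years", {
  set.seed(66)
  series <- lapply(1:6, function(i)
    ring_series(paste0("D", i), 1900 + 10 * i,
                runif(60, 1, 2), latitude = 60))
  ch <- build_chronology(series, min_depth = 5, prewhiten = FALSE)
  yrs_all <- sort(unique(unlist(lapply(series, proxyrel:::ring_years))))
  depth <- vapply(yrs_all, function(y)
    sum(vapply(series, function(s) y %in% proxyrel:::ring_years(s), TRUE)), 1L)
  expect_setequal(ch$index$years, yrs_all[depth >= 5])
  expect_true(all(ch$sample_depth >= 5))
})

test_that("latitude split sends the boundary north and flags missing sites", {
  mk <- function(id, lat) ring_series(id, 2000, rep(1, 12), latitude = lat)
  sp <- split_by_latitude(list(mk("a", 60.2), mk("b", 67.4), mk("c", 66.5)))
  expect_equal(vapply(sp$south, function(s) s$id, ""), "a")
  expect_setequal(vapply(sp$north, function(s) s$id, ""), c("b", "c"))
  expect_error(split_by_latitude(list(mk("a", 60), mk("nolat", NA))), "nolat")
  empty <- split_by_latitude(list())
  expect_length(empty$south, 0)
  expect_length(empty$north, 0)
})
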