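mk_series <- function(value, start_bce = 2850, step = 25) {
  n <- length(value)
  data.frame(year_bce = seq(start_bce, by = -step, length.out = n),
             value = value)
}

test_that("linear detrending removes exactly the OLS line", {
  t <- 0:199
  # perfectly linear -> all-zero residual
  lin <- mk_series(3 + 0.02 * t, step = 1)
  expect_lt(max(abs(detrend(lin)$value)), 1e-9)
  # constant -> zero residual
  expect_lt(max(abs(detrend(mk_series(rep(5, 50)))$value)), 1e-12)
  # linear + oscillation orthogonal to the trend -> residual is the oscillation
  osc <- cos(2 * pi * 3 * (t - mean(t)) / 200) # 3 full periods, centered
  both <- mk_series(2 + 0.01 * t + osc, step = 1)
  expect_lt(max(abs(detrend(both)$value - osc)), 1e-8)
  # residual mean is zero
  set.seed(61)
  expect_lt(abs(mean(detrend(mk_series(runif(40)))$value)), 1e-9)
  expect_error(detrend(mk_series(c(1, 2))), "at least 3")
})

test_that("binning takes block means labelled at midpoints", {
  # constant series stays constant
  cb <- bin_series(mk_series(rep(2, 40), step = 25), width = 50)
  expect_true(all(cb$value == 2))
  # annual ramp 1..100, width 50 -> block means 25.5 and 75.5
  ramp <- mk_series(1:100, start_bce = 2850, step = 1)
  b <- bin_series(ramp, width = 50)
  expect_equal(b$value, c(25.5, 75.5))
  expect_equal(nrow(b), 2)
  # random series equals an independent block-mean oracle
  set.seed(62)
  v <- rnorm(103)
  s <- mk_series(v, step = 1)
  b2 <- bin_series(s, width = 25)
  oracle <- sapply(1:4, function(k) mean(v[((k - 1) * 25 + 1):(k * 25)]))
  expect_equal(b2$value, oracle, tolerance = 1e-12)
  expect_equal(attr(b2, "n_dropped"), 3) # trailing partial bin reported
})

test_that("windowed Pearson correlation is affine-invariant and signed", {
  set.seed(63)
  a <- mk_series(rnorm(47))
  expect_equal(window_pearson(a, a), 1)
  neg <- a; neg$value <- -a$value
  expect_equal(window_pearson(a, neg), -1)
  b <- mk_series(rnorm(47))
  r0 <- window_pearson(a, b, window = c(2850, 2350))
  b2 <- b; b2$value <- 3 * b$value - 7 # affine rescaling
  expect_equal(window_pearson(a, b2, window = c(2850, 2350)), r0,
               tolerance = 1e-12)
  flat <- a; flat$value <- rep(1, nrow(a))
  expect_error(window_pearson(a, flat), "zero variance")
})

test_that("cross-correlation recovers a constructed shift", {
  set.seed(64)
  n <- 60
  base <- cumsum(rnorm(n))
  a <- mk_series(base)
  # b is a delayed by 4 bins of 25 yr = +100 yr (a leads b)
  b <- mk_series(c(rep(0, 4), base[1:(n - 4)]))
  xc <- cross_correlation(a, b, max_lag = 200)
  expect_equal(attr(xc, "best_lag"), 100)
  expect_gt(attr(xc, "best_r"), 0.9)
  # self-correlation peaks at lag 0 with r = 1
  xs <- cross_correlation(a, a, max_lag = 100)
  expect_equal(attr(xs, "best_lag"), 0)
  expect_equal(attr(xs, "best_r"), 1)
})

test_that("cross-correlation is antisymmetric in its arguments", {
  set.seed(65)
  a <- mk_series(rnorm(50)); b <- mk_series(rnorm(50))
  ab <- cross_correlation(a, b, max_lag = 150)
  ba <- cross_correlation(b, a, max_lag = 150)
  expect_equal(ab$r, rev(ba$r), tolerance = 1e-12)
})

test_that("white-noise pairs rarely show spurious lagged correlation", {
  hits <- 0
  for (i in 1:100) {
    set.seed(6500 + i)
    a <- mk_series(rnorm(200)); b <- mk_series(rnorm(200))
    xc <- cross_correlation(a, b, max_lag = 250)
    if (max(abs(xc$r)) < 0.3) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("autocorrelation matches known processes", {
  # lag 0 -> 1
  set.seed(66)
  a <- mk_series(rnorm(100))
  ac <- autocorrelation(a, max_lag = 100)
  expect_equal(ac$r[ac$lag == 0], 1)
  # period-T sinusoid: local maximum at lag T (200 yr on 25-yr bins)
  t <- seq(0, by = 25, length.out = 120)
  sine <- mk_series(sin(2 * pi * t / 200))
  acs <- autocorrelation(sine, max_lag = 300)
  pos <- acs[acs$lag > 0, ]
  expect_equal(pos$lag[which.max(pos$r)], 200)
  # AR(1) with phi = 0.8: lag-1 autocorrelation near 0.8 at 500 bins
  set.seed(67)
  ar <- mk_series(as.numeric(arima.sim(list(ar = 0.8), 500)))
  aca <- autocorrelation(ar, max_lag = 25)
  expect_lt(abs(aca$r[aca$lag == 25] - 0.8), 0.1)
})

test_that("SD-threshold event detection matches hand-computed z-scores", {
  x <- mk_series(c(0, 0, 3, 3, 0, -3, 0))
  ev <- detect_events(x, k = 1)
  # independent oracle: z = (x - mean)/sd by hand
  v <- c(0, 0, 3, 3, 0, -3, 0)
  z <- (v - mean(v)) / sd(v)
  expect_equal(which(z >= 1), c(3, 4))
  expect_equal(which(z <= -1), 6)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$sign, c("positive", "negative"))
  expect_equal(ev$start_bce[1], x$year_bce[3])
  expect_equal(ev$end_bce[1], x$year_bce[4])
  expect_equal(ev$start_bce[2], x$year_bce[6])
  expect_equal(ev$peak_z[1], max(z), tolerance = 1e-12)
})

test_that("an injected boxcar yields exactly one positive interval", {
  v <- rep(0, 100)
  v[40:50] <- 2 # 2-SD-scale boxcar on a flat background
  x <- mk_series(v, step = 1)
  ev <- detect_events(x, k = 1.5)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$sign, "positive")
  expect_equal(ev$start_bce, x$year_bce[40])
  expect_equal(ev$end_bce, x$year_bce[50])
})

test_that("event detection on noise flags about the Gaussian tail mass", {
  set.seed(68)
  x <- mk_series(rnorm(1000), step = 1)
  ev <- detect_events(x, k = 3)
  flagged <- if (nrow(ev) == 0) 0 else
    sum(ev$start_bce - ev$end_bce + 1)
  expect_lte(flagged, 10) # ~0.27% of 1000 years expected
})

test_that("negating the series mirrors the event signs exactly", {
  set.seed(69)
  v <- rnorm(200) + c(rep(0, 80), rep(2.5, 20), rep(0, 100))
  x <- mk_series(v, step = 1)
  nx <- x; nx$value <- -x$value
  e1 <- detect_events(x, k = 1.5)
  e2 <- detect_events(nx, k = 1.5)
  expect_equal(e1$start_bce, e2$start_bce)
  expect_equal(e1$end_bce, e2$end_bce)
  expect_equal(e1$sign, ifelse(e2$sign == "positive", "negative", "positive"))
  expect_equal(e1$peak_z, -e2$peak_z, tolerance = 1e-12)
  flat <- mk_series(rep(1, 30))
  expect_error(detect_events(flat), "degenerate")
})

test_that("envelope-aware mode only flags whole-envelope excursions", {
  v <- c(rep(0, 20), rep(3, 5), rep(0, 20))
  df <- mk_series(v, step = 1)
  df$lower <- df$value - 0.5
  df$upper <- df$value + 0.5
  strict <- detect_events(df, k = 1.5, require_envelope = TRUE)
  expect_equal(nrow(strict), 1)
  # widen the envelope so the lower bound never crosses: no event
  df$lower <- df$value - 10
  none <- detect_events(df, k = 1.5, require_envelope = TRUE)
  expect_equal(nrow(none), 0)
})
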