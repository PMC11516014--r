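test_that("date filters apply the three rules in order and audit the counts", {
  cc <- identity_curve(2500, 6000)
  d <- toy_dates(c(4100, 4100, 4200, 9999), c(150, 30, 30, 30),
                 material = c("charcoal", "shell", "charcoal", "charcoal"))
  # row 1: error 150 > 100; row 2: shell; row 4: 9999 BP is way out of window
  # (and outside curve coverage in calendar terms after the median rule);
  # rows 3 survives; also add one in-window survivor
  d$c14_age[4] <- 5900 # median ~ 3951 BCE, outside 2950-1600
  f <- apply_filters(d, cc)
  audit <- attr(f, "audit")
  expect_equal(nrow(f), 1)
  expect_equal(unname(audit["error"]), 1)
  expect_equal(unname(audit["marine"]), 1)
  expect_equal(unname(audit["window"]), 1)
  expect_equal(unname(audit["n_out"]), 1)
  # two valid in-window dates, one high-error, one shell -> 2 survivors
  d2 <- toy_dates(c(4100, 4200, 4100, 4150), c(30, 30, 150, 30),
                  material = c("charcoal", "charcoal", "charcoal", "shell"))
  f2 <- apply_filters(d2, cc)
  expect_equal(nrow(f2), 2)
  expect_equal(unname(attr(f2, "audit")[c("error", "marine")]), c(1, 1))
})

test_that("empty input passes the filters with a zeroed audit", {
  cc <- identity_curve(2500, 6000)
  d <- toy_dates(numeric(0), numeric(0))
  f <- apply_filters(d, cc)
  expect_equal(nrow(f), 0)
  expect_true(all(attr(f, "audit") == 0))
})

test_that("SPD is the cellwise sum of calibrated densities", {
  cc <- wiggly_curve_20()
  ax <- study_axis()
  # single date: SPD identical to its calibrated density
  d1 <- toy_dates(4100, 30)
  s1 <- spd(d1, cc, ax)
  expect_equal(s1$value * ax$step, calibrate(4100, 30, cc, ax)$mass)
  # two dates with (effectively) disjoint supports: total mass 2
  d2 <- toy_dates(c(3800, 4900), c(20, 20))
  s2 <- spd(d2, cc, ax)
  expect_equal(sum(s2$value) * ax$step, 2, tolerance = 1e-6)
  # 10 dates against an independent loop-and-add oracle
  set.seed(21)
  ages <- sample(3750:4650, 10)
  d10 <- toy_dates(ages, 35)
  s10 <- spd(d10, cc, ax)
  oracle <- rep(0, length(ax$bce))
  for (a in ages) oracle <- oracle + calibrate(a, 35, cc, ax)$mass
  expect_equal(s10$value * ax$step, oracle, tolerance = 1e-12)
})

test_that("SPD is additive over dataset unions and conserves mass", {
  cc <- wiggly_curve_20()
  ax <- study_axis()
  set.seed(22)
  A <- toy_dates(sample(3700:4900, 6), 30)
  B <- toy_dates(sample(3700:4900, 4), 40)
  sAB <- spd(rbind(A, B), cc, ax)
  expect_equal(sAB$value, spd(A, cc, ax)$value + spd(B, cc, ax)$value,
               tolerance = 1e-12)
  expect_equal(sum(sAB$value) * ax$step, 10, tolerance = 1e-6)
})

test_that("SPD correlation behaves as a Pearson r and rejects degeneracy", {
  cc <- wiggly_curve_20()
  ax <- study_axis()
  set.seed(23)
  s <- spd(toy_dates(sample(3700:4900, 8), 30), cc, ax)
  expect_equal(spd_correlation(s, s), 1)
  s0 <- s; s0$value <- rep(1, length(s0$value))
  expect_error(spd_correlation(s, s0), "zero variance")
  # normalized vs unnormalized SPDs of the same dates correlate strongly
  d <- toy_dates(sample(3700:4900, 30), 35)
  expect_gt(spd_correlation(spd(d, cc, ax, normalized = TRUE),
                            spd(d, cc, ax, normalized = FALSE)), 0.9)
})

test_that("composite KDE handles degenerate input and integrates to 1", {
  cc <- identity_curve(2500, 6000)
  ax <- study_axis()
  # n identical precise dates: mean curve unimodal, mode within bandwidth
  d <- toy_dates(rep(4200, 12), 1) # 4200 BP = 2251 BCE
  set.seed(24)
  m <- composite_kde(d, cc, ax, bandwidth = 50, n_sim = 25)
  expect_equal(sum(m$mean) * ax$step, 1, tolerance = 1e-6)
  expect_true(all(abs(rowSums(m$ensemble) * ax$step - 1) < 1e-6))
  mode_bce <- ax$bce[which.max(m$mean)]
  expect_lt(abs(mode_bce - 2251), 50)
  # unimodal where the density is non-negligible: one local maximum
  keep <- which(m$mean > 0.01 * max(m$mean))
  dm <- diff(m$mean[keep])
  expect_lte(sum(diff(sign(dm[dm != 0])) != 0), 1)
  expect_true(all(m$lower <= m$mean + 1e-12) && all(m$mean <= m$upper + 1e-12))
  expect_error(composite_kde(d, cc, ax, n_sim = 1), "n_sim")
  expect_error(composite_kde(d[1, ], cc, ax), "at least 2")
})

test_that("duplicating the dataset leaves the KDE mean shape unchanged", {
  cc <- wiggly_curve_20()
  ax <- study_axis()
  set.seed(25)
  d <- toy_dates(sample(3700:4900, 60, replace = TRUE), 35)
  m1 <- composite_kde(d, cc, ax, n_sim = 150)
  m2 <- composite_kde(rbind(d, d), cc, ax, n_sim = 150)
  rms <- sqrt(mean((m1$mean - m2$mean)^2))
  expect_lt(rms / diff(range(m1$mean)), 0.05) # Monte Carlo tolerance
})

test_that("the KDE mean is stable in the ensemble size", {
  cc <- wiggly_curve_20()
  ax <- study_axis()
  set.seed(26)
  d <- toy_dates(sample(3700:4900, 80, replace = TRUE), 35)
  m1 <- composite_kde(d, cc, ax, n_sim = 300, boot = FALSE)
  m2 <- composite_kde(d, cc, ax, n_sim = 600, boot = FALSE)
  rms <- sqrt(mean((m1$mean - m2$mean)^2))
  expect_lt(rms / diff(range(m1$mean)), 0.02)
})

test_that("growth rates follow the annualized closed form", {
  ax <- cal_axis(2950, 1600)
  G <- length(ax$bce)
  fake <- function(rows) {
    structure(list(axis = ax, ensemble = rows, mean = colMeans(rows),
                   lower = rows[1, ], upper = rows[1, ], bandwidth = 50,
                   n_sim = nrow(rows), boot = FALSE, n_dates = 10),
              class = "ckde_model")
  }
  # constant density -> zero growth everywhere
  g0 <- kde_growth(fake(matrix(1 / G, 2, G)), window = 25)
  expect_true(all(abs(g0$value) < 1e-12))
  # K(t) = e^{rt} -> g = e^r - 1 uniformly
  r <- 5e-4
  t_fwd <- ax$start_bce - ax$bce
  K <- matrix(exp(r * t_fwd), 1, G, byrow = TRUE)
  g1 <- kde_growth(fake(rbind(K, K)), window = 25)
  expect_equal(g1$value, rep(exp(r) - 1, G - 25), tolerance = 1e-9)
  # arbitrary toy curve vs independent cell-by-cell oracle
  set.seed(27)
  K2 <- matrix(runif(G, 0.5, 2), 1, G)
  g2 <- kde_growth(fake(rbind(K2, K2)), window = 25)
  oracle <- sapply(seq_len(G - 25), function(i) {
    (K2[1, i + 25] / K2[1, i])^(1 / 25) - 1
  })
  expect_equal(g2$value, oracle, tolerance = 1e-12)
  # zero cells are masked, not propagated
  K3 <- K2; K3[1, 40] <- 0
  g3 <- kde_growth(fake(rbind(K3, K3)), window = 25)
  expect_true(is.na(g3$rates[1, 40]) && is.na(g3$rates[1, 15]))
})

test_that("the exponential null test is internally consistent on null data", {
  cc <- synthetic_calcurve(3000, 5500)
  ax <- study_axis()
  set.seed(28)
  traj <- population_trajectory(ax, "exponential", rate = 0.0008)
  d <- simulate_dates(traj, 120, cc)
  nt <- exp_null_test(d, cc, ax, n_sim = 60)
  # definitions agree: no deviation intervals iff SPD never exits envelope
  outside <- sum(nt$observed > nt$upper | nt$observed < nt$lower)
  if (nrow(nt$intervals) == 0) {
    expect_equal(outside, 0)
    expect_gt(nt$p_value, 0.05)
  } else {
    expect_equal(sum(nt$intervals$start_bce - nt$intervals$end_bce + 1),
                 outside)
  }
  expect_gt(nt$coef["lambda"], 0) # growth direction recovered
  expect_error(exp_null_test(d[1:5, ], cc, ax), "at least 10")
})

test_that("the null test flags an injected boom with a positive interval", {
  cc <- synthetic_calcurve(3000, 5500)
  ax <- study_axis()
  set.seed(29)
  seg <- data.frame(start_bce = c(2950, 2350, 2199),
                    end_bce = c(2351, 2200, 1600),
                    level = c(1, 3, 1)) # 3x boom over 150 yr
  traj <- population_trajectory(ax, "piecewise", segments = seg)
  d <- simulate_dates(traj, 400, cc)
  nt <- exp_null_test(d, cc, ax, n_sim = 60)
  pos <- nt$intervals[nt$intervals$sign == "positive", , drop = FALSE]
  overlaps_boom <- any(pos$start_bce >= 2200 & pos$end_bce <= 2350)
  expect_true(nrow(pos) > 0 && overlaps_boom)
  expect_lt(nt$p_value, 0.05)
})

test_that("site binning weights clustered dates as one unit", {
  cc <- identity_curve(2500, 6000)
  ax <- study_axis()
  # 3 dates at one site within 100 14C yr -> one bin; 1 lone date elsewhere
  d <- toy_dates(c(4100, 4150, 4120, 4500), 30,
                 site_id = c("a", "a", "a", "b"))
  s <- spd(d, cc, ax, bin_h = 100)
  expect_equal(s$n_bins, 2)
  expect_equal(sum(s$value) * ax$step, 2, tolerance = 1e-6)
})
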