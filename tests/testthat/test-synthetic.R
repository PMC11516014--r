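test_that("trajectory families produce the stated density shapes", {
  ax <- study_axis()
  expect_true(all(population_trajectory(ax, "constant")$density == 1))
  ex <- population_trajectory(ax, "exponential", rate = 0.001)
  t_fwd <- ax$start_bce - ax$bce
  expect_equal(ex$density, exp(0.001 * t_fwd), tolerance = 1e-12)
  lg <- population_trajectory(ax, "logistic", rate = 0.01,
                              midpoint_bce = 2300)
  expect_equal(lg$density[ax$bce == 2300], 0.5, tolerance = 1e-9)
  expect_true(all(diff(lg$density) >= 0))
  pw <- population_trajectory(ax, "piecewise", segments = data.frame(
    start_bce = 2500, end_bce = 2300, level = 2))
  expect_equal(sort(unique(pw$density)), c(0, 2))
  expect_error(population_trajectory(ax, "piecewise", segments = data.frame(
    start_bce = 2500, end_bce = 2300, level = 0)), "positive cell")
})

test_that("dates simulated from a constant trajectory are uniform in time", {
  cc <- identity_curve(2500, 6000)
  ax <- study_axis()
  traj <- population_trajectory(ax, "constant")
  set.seed(71)
  d <- simulate_dates(traj, 1e4, cc)
  expect_equal(nrow(d), 1e4)
  counts <- table(cut(d$true_year_bce, breaks = 20))
  expect_gt(chisq.test(counts)$p.value, 0.01)
  # n = 1 -> exactly one record
  expect_equal(nrow(simulate_dates(traj, 1, cc)), 1)
  expect_error(simulate_dates(traj, 0, cc), ">= 1")
})

test_that("an exponential trajectory's rate is recovered by MLE on the events", {
  cc <- identity_curve(2500, 6000)
  ax <- study_axis()
  lambda <- 0.001
  traj <- population_trajectory(ax, "exponential", rate = lambda)
  set.seed(72)
  d <- simulate_dates(traj, 2000, cc)
  t_ev <- ax$start_bce - d$true_year_bce
  TT <- ax$start_bce - ax$end_bce
  # MLE for a window-truncated exponential (independent of the generator)
  nll <- function(l) -(length(t_ev) * log(l) + l * sum(t_ev) -
                         length(t_ev) * log(exp(l * TT) - 1))
  lhat <- optimize(nll, c(1e-5, 0.01))$minimum
  expect_lt(abs(lhat - lambda) / lambda, 0.10)
})

test_that("simulated dates carry plausible lab structure and provenance", {
  cc <- identity_curve(2500, 6000)
  ax <- study_axis()
  traj <- population_trajectory(ax, "constant")
  set.seed(73)
  d <- simulate_dates(traj, 500, cc,
                      lab_error_model = list(type = "uniform", lo = 20, hi = 80),
                      site_model = list(k = 10, concentration = 0.5))
  expect_true(all(d$error >= 20 & d$error <= 80))
  expect_lte(length(unique(d$site_id)), 10)
  expect_equal(attr(d, "provenance")$generator, "simulate_dates")
  emp <- simulate_dates(traj, 300, cc,
                        lab_error_model = list(type = "empirical",
                                               errors = c(25, 40, 60)))
  expect_true(all(emp$error %in% c(25, 40, 60)))
})

test_that("artifact simulation conserves mass within the typology spans", {
  ax <- study_axis()
  traj <- population_trajectory(ax, "constant")
  one_type <- data.frame(category = "battle_axe", type_code = "X",
                         span_start = 2500, span_end = 2401)
  set.seed(74)
  arts <- simulate_artifacts(traj, 50, one_type)
  s <- aoristic_sum(arts, ax)
  expect_equal(sum(s$value), nrow(arts), tolerance = 1e-9)
  expect_true(all(s$value[ax$bce > 2500 | ax$bce < 2401] == 0))
  # deposition years outside any span are dropped and counted
  expect_equal(nrow(arts) + attr(arts, "n_dropped"), 50)
  # two abutting types: summed series supported on the union of spans
  two <- rbind(one_type,
               data.frame(category = "battle_axe", type_code = "Y",
                          span_start = 2400, span_end = 2301))
  set.seed(75)
  a2 <- simulate_artifacts(traj, 200, two)
  s2 <- aoristic_sum(a2, ax)
  expect_true(all(s2$value[ax$bce <= 2500 & ax$bce >= 2301] > 0))
  expect_true(all(s2$value[ax$bce > 2500 | ax$bce < 2301] == 0))
})

test_that("a deposition boom is recovered by the aoristic peak bin", {
  ax <- study_axis()
  seg <- data.frame(start_bce = c(2950, 2500, 2399),
                    end_bce = c(2501, 2400, 1600),
                    level = c(1, 8, 1))
  traj <- population_trajectory(ax, "piecewise", segments = seg)
  # narrow 25-yr subtypes tiling the window
  starts <- seq(2950, 1625, by = -25)
  ty <- data.frame(category = "battle_axe",
                   type_code = sprintf("T%03d", seq_along(starts)),
                   span_start = starts, span_end = starts - 24)
  set.seed(76)
  arts <- simulate_artifacts(traj, 2000, ty)
  s <- aoristic_sum(arts, ax)
  b <- bin_series(as_series(s), width = 25, stat = sum)
  peak_bin <- b$year_bce[which.max(b$value)]
  true_peak <- (2500 + 2400) / 2
  expect_lt(abs(peak_bin - true_peak), 50)
})

test_that("pollen end members behave as declared", {
  prof <- default_pollen_profiles()
  expect_equal(sum(prof$forest), 1, tolerance = 1e-12)
  expect_equal(sum(prof$open), 1, tolerance = 1e-12)
  # o = 0: counts multinomial around the forest profile; flat score
  set.seed(77)
  p0 <- simulate_pollen(function(y) rep(0, length(y)), records = 2,
                        samples_per_record = 25, grains = 500)
  props <- colMeans(as.matrix(p0[attr(p0, "taxa")]) / 500)
  expect_lt(max(abs(props - prof$forest)), 0.02)
  f0 <- suppressWarnings(openness_pca(p0)) # open taxa absent: dropped
  # no openness trend: score uncorrelated with age
  expect_lt(abs(cor(f0$scores$score, f0$scores$age_bce)), 0.5)
  # o = 1 vs o = 0 records separate completely on PC1
  set.seed(78)
  p1 <- simulate_pollen(function(y) rep(1, length(y)), records = 2,
                        samples_per_record = 25, grains = 500)
  p1$record_id <- sub("core", "open", p1$record_id)
  p1$sample_id <- sub("core", "open", p1$sample_id)
  fit <- openness_pca(rbind(p0, p1))
  s_open <- fit$scores$score[grepl("open", fit$scores$record_id)]
  s_forest <- fit$scores$score[!grepl("open", fit$scores$record_id)]
  expect_gt(min(s_open), max(s_forest))
  expect_error(simulate_pollen(function(y) 0, forest_profile = c(a = 0.5)),
               "sum to 1")
})

test_that("a ramp openness trajectory is recovered regionally (r > 0.9)", {
  set.seed(79)
  ramp <- function(y) (4800 - y) / 4100
  pol <- simulate_pollen(ramp, records = 3, samples_per_record = 40,
                         grains = 300, age_jitter_sd = 25)
  fit <- openness_pca(pol)
  rmap <- stats::setNames(rep("NJ", 3), unique(pol$record_id))
  ro <- regional_openness(fit, rmap)
  truth <- ramp(ro$NJ$axis$bce)
  ok <- !is.na(ro$NJ$value)
  expect_gt(cor(ro$NJ$value[ok], truth[ok]), 0.9)
})

test_that("all generators are deterministic under a fixed seed", {
  cc <- identity_curve(2500, 6000)
  ax <- study_axis()
  traj <- population_trajectory(ax, "exponential", rate = 0.001)
  set.seed(80); d1 <- simulate_dates(traj, 100, cc)
  set.seed(80); d2 <- simulate_dates(traj, 100, cc)
  expect_identical(d1, d2)
  set.seed(80); a1 <- simulate_artifacts(traj, 100)
  set.seed(80); a2 <- simulate_artifacts(traj, 100)
  expect_identical(a1, a2)
  set.seed(80); p1 <- simulate_pollen(function(y) rep(0.5, length(y)))
  set.seed(80); p2 <- simulate_pollen(function(y) rep(0.5, length(y)))
  expect_identical(p1, p2)
})
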