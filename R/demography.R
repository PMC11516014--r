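#' Filter a radiocarbon dataset for demographic modelling
#'
#' Applies the standard dates-as-data source-critical filters, in order:
#' (1) remove determinations with laboratory error above `error_max`
#' (default 100 14C yr); (2) remove marine-influenced materials (default:
#' shell, to avoid reservoir effects); (3) remove dates whose calibrated
#' median falls outside the observation window padded by 100 years
#' (default 2950--1600 BCE for a 2850--1700 BCE window, avoiding boundary
#' effects). An audit of counts removed per rule, in application order,
#' travels with the result.
#'
#' @param dates canonical date table (see [read_dates_csv()]).
#' @param curve calibration curve used for the median-date rule.
#' @param error_max maximum laboratory error kept (14C yr).
#' @param window_bce `c(oldest, youngest)` years BCE of the padded window.
#' @param exclude_classes material classes removed as marine-influenced.
#' @param lookup material-class lookup table, see [material_class()].
#' @return The filtered date table, with attribute `audit`: named integer
#'   vector `c(n_in, error, marine, window, n_out)`.
#' @export
apply_filters <- function(dates, curve, error_max = 100,
                          window_bce = c(2950, 1600),
                          exclude_classes = "shell",
                          lookup = default_material_lookup()) {
  n_in <- nrow(dates)
  audit <- c(n_in = n_in, error = 0L, marine = 0L, window = 0L, n_out = 0L)
  if (n_in == 0) {
    attr(dates, "audit") <- audit
    return(dates)
  }
  keep <- dates$error <= error_max
  audit["error"] <- sum(!keep)
  dates <- dates[keep, , drop = FALSE]

  cls <- material_class(dates$material, lookup)
  keep <- !(cls %in% exclude_classes)
  audit["marine"] <- sum(!keep)
  dates <- dates[keep, , drop = FALSE]

  if (nrow(dates) > 0) {
    med <- calibrated_median(dates$c14_age, dates$error, curve, window_bce)
    keep <- !is.na(med) & med <= window_bce[1] & med >= window_bce[2]
    audit["window"] <- sum(!keep)
    dates <- dates[keep, , drop = FALSE]
  }
  audit["n_out"] <- nrow(dates)
  rownames(dates) <- NULL
  attr(dates, "audit") <- audit
  dates
}

# Calibrated median year (BCE) per determination, computed on an annual
# axis spanning the window padded by 3000 yr (clipped to curve coverage).
calibrated_median <- function(c14_age, error, curve, window_bce, pad = 3000) {
  lo_bce <- max(1, window_bce[2] - pad,
                ceiling(calbp_safe(min(curve$theta))))
  hi_bce <- min(window_bce[1] + pad, floor(calbp_safe(max(curve$theta))))
  ax <- cal_axis(hi_bce, lo_bce, 1)
  P <- calibrate_matrix(c14_age, error, curve, ax)
  vapply(seq_len(ncol(P)), function(j) {
    cs <- cumsum(P[, j])
    ax$bce[which(cs >= 0.5)[1]]
  }, numeric(1))
}

# curve theta (cal BP) to BCE, returning -Inf/clamped when out of BCE range
calbp_safe <- function(calbp) calbp - 1949

#' Summed probability distribution of radiocarbon dates
#'
#' Sums the calibrated densities of all dates cell by cell: `S(theta) =
#' sum_i p_i(theta)`, the classic dates-as-data population-activity
#' proxy. No site binning is applied by default; pass `bin_h` to cluster
#' dates within a site closer than `bin_h` 14C years and weight each
#' cluster equally (a guard against over-sampled single sites).
#'
#' @param dates canonical date table.
#' @param curve calibration curve.
#' @param axis calendar axis.
#' @param normalized calibrate each date to unit mass first (default TRUE).
#' @param bin_h optional site-binning threshold in 14C years; `NULL`
#'   (default) disables binning.
#' @return Object of class `spd_series`: `axis`, `value` (summed
#'   probability per year), `n_dates`, `n_bins`, `normalized`. In
#'   normalized mode `sum(value) * step` equals the number of dates (or
#'   bins).
#' @export
spd <- function(dates, curve, axis, normalized = TRUE, bin_h = NULL) {
  if (nrow(dates) == 0) stop("no dates supplied")
  P <- calibrate_matrix(dates$c14_age, dates$error, curve, axis,
                        normalized = normalized)
  if (is.null(bin_h)) {
    w <- rep(1, nrow(dates))
    n_bins <- nrow(dates)
  } else {
    bins <- site_bins(dates, bin_h)
    w <- 1 / ave(rep(1, length(bins)), bins, FUN = sum)
    n_bins <- length(unique(bins))
  }
  value <- as.numeric(P %*% w) / axis$step
  structure(
    list(axis = axis, value = value, n_dates = nrow(dates),
         n_bins = n_bins, normalized = normalized),
    class = "spd_series"
  )
}

#' Cluster dates within sites for SPD binning
#'
#' Single-linkage clustering of uncalibrated ages within each site; dates
#' closer than `h` 14C years share a bin.
#'
#' @param dates canonical date table.
#' @param h clustering threshold (14C yr), default 100.
#' @return character vector of bin identifiers, one per date.
#' @export
site_bins <- function(dates, h = 100) {
  out <- character(nrow(dates))
  for (s in unique(dates$site_id)) {
    i <- which(dates$site_id == s)
    if (length(i) == 1) {
      out[i] <- paste0(s, "_1")
    } else {
      hc <- stats::hclust(stats::dist(dates$c14_age[i]), method = "single")
      out[i] <- paste0(s, "_", stats::cutree(hc, h = h))
    }
  }
  out
}

#' @export
print.spd_series <- function(x, ...) {
  cat(sprintf(
    "SPD of %d dates on %d-%d BCE (%s); total mass %.3f\n",
    x$n_dates, as.integer(x$axis$start_bce), as.integer(x$axis$end_bce),
    if (x$normalized) "normalized" else "non-normalized",
    sum(x$value) * x$axis$step
  ))
  invisible(x)
}

#' @export
as.data.frame.spd_series <- function(x, ...) {
  data.frame(year_bce = x$axis$bce, value = x$value)
}

#' Pearson correlation between two SPDs (or any aligned series)
#'
#' Standard product-moment correlation over grid cells; used e.g. to
#' compare normalised vs non-normalised SPDs or all-material vs
#' short-lived-only SPDs.
#'
#' @param a,b `spd_series` objects (or any objects whose
#'   [as.data.frame()] yields `year_bce`/`value`) on identical axes.
#' @return Pearson r.
#' @export
spd_correlation <- function(a, b) {
  da <- as.data.frame(a); db <- as.data.frame(b)
  if (nrow(da) != nrow(db) || any(da$year_bce != db$year_bce)) {
    stop("series are not on identical axes")
  }
  if (stats::sd(da$value) == 0 || stats::sd(db$value) == 0) {
    stop("undefined correlation: a series has zero variance")
  }
  stats::cor(da$value, db$value)
}

#' Bootstrap composite kernel density model of radiocarbon dates
#'
#' A more robust alternative to the SPD that carries sampling error and
#' chronological uncertainty explicitly. Each of `n_sim` simulations
#' (i) resamples the `n` dates with replacement (when `boot = TRUE`),
#' (ii) draws one calendar year per sampled date from its calibrated
#' density, and (iii) computes a Gaussian kernel density estimate with a
#' fixed bandwidth (default 50 yr) on the annual axis, renormalized to
#' unit mass. The ensemble is summarized by its pointwise mean and a
#' 2.5/97.5-percentile uncertainty envelope.
#'
#' @param dates canonical date table (>= 2 rows).
#' @param curve calibration curve.
#' @param axis calendar axis.
#' @param bandwidth Gaussian kernel standard deviation in years.
#' @param n_sim ensemble size (>= 2), default 1000.
#' @param boot bootstrap-resample the dates each simulation (default TRUE);
#'   `FALSE` keeps the full set and only propagates calibration
#'   uncertainty.
#' @return Object of class `ckde_model`: `axis`, `ensemble` (n_sim x
#'   grid matrix of densities per year, each row summing to 1/step),
#'   `mean`, `lower`, `upper`, `bandwidth`, `n_sim`, `boot`, `n_dates`.
#' @export
composite_kde <- function(dates, curve, axis, bandwidth = 50, n_sim = 1000,
                          boot = TRUE) {
  if (nrow(dates) < 2) stop("composite_kde needs at least 2 dates")
  if (n_sim < 2) stop("n_sim must be >= 2")
  P <- calibrate_matrix(dates$c14_age, dates$error, curve, axis)
  cdf <- apply(P, 2, cumsum)
  n <- ncol(P)
  G <- length(axis$bce)
  from <- axis$end_bce; to <- axis$start_bce
  ens <- matrix(NA_real_, nrow = n_sim, ncol = G)
  for (r in seq_len(n_sim)) {
    idx <- if (boot) sample.int(n, n, replace = TRUE) else seq_len(n)
    u <- stats::runif(n)
    yi <- vapply(seq_len(n), function(j) {
      findInterval(u[j], cdf[, idx[j]]) + 1L
    }, integer(1))
    years <- axis$bce[yi]
    d <- stats::density(years, bw = bandwidth, kernel = "gaussian",
                        from = from, to = to, n = G)
    y <- rev(d$y) # axis is descending BCE
    ens[r, ] <- y / (sum(y) * axis$step)
  }
  structure(
    list(axis = axis, ensemble = ens, mean = colMeans(ens),
         lower = apply(ens, 2, stats::quantile, 0.025),
         upper = apply(ens, 2, stats::quantile, 0.975),
         bandwidth = bandwidth, n_sim = n_sim, boot = boot, n_dates = n),
    class = "ckde_model"
  )
}

#' @export
print.ckde_model <- function(x, ...) {
  cat(sprintf(
    "Composite KDE model: %d dates, %d simulations (bootstrap %s), bandwidth %g yr\n",
    x$n_dates, x$n_sim, if (x$boot) "on" else "off", x$bandwidth
  ))
  cat(sprintf("  axis %d-%d BCE; mean-curve mode at %d BCE\n",
              as.integer(x$axis$start_bce), as.integer(x$axis$end_bce),
              as.integer(x$axis$bce[which.max(x$mean)])))
  invisible(x)
}

#' @export
summary.ckde_model <- function(object, ...) {
  mode_bce <- object$axis$bce[which.max(object$mean)]
  env_width <- mean(object$upper - object$lower)
  out <- list(n_dates = object$n_dates, n_sim = object$n_sim,
              bandwidth = object$bandwidth, mode_bce = mode_bce,
              mean_envelope_width = env_width,
              mass = sum(object$mean) * object$axis$step)
  class(out) <- "summary.ckde_model"
  out
}

#' @export
print.summary.ckde_model <- function(x, ...) {
  cat(sprintf(
    paste0("Composite KDE summary: %d dates, %d sims, bw %g yr\n",
           "  mean-curve mode: %d BCE; total mass %.6f\n",
           "  mean 95%% envelope width: %.3g (density per year)\n"),
    x$n_dates, x$n_sim, x$bandwidth, as.integer(x$mode_bce), x$mass,
    x$mean_envelope_width
  ))
  invisible(x)
}

#' @export
as.data.frame.ckde_model <- function(x, ...) {
  data.frame(year_bce = x$axis$bce, value = x$mean,
             lower = x$lower, upper = x$upper)
}

#' Annualized growth rates from a composite KDE model
#'
#' The growth rate measures the fractional change of the density over a
#' forward-looking window of `window` years, annualized geometrically:
#' `g(t) = (K(t + w) / K(t))^(1/w) - 1`. Computed per ensemble row and
#' summarized by the pointwise mean and 2.5/97.5-percentile envelope
#' (set `on = "mean"` to compute from the mean curve only).
#'
#' @param model a `ckde_model`.
#' @param window growth window in years (default 25).
#' @param on `"ensemble"` (default) or `"mean"`.
#' @return Object of class `growth_series`: `axis` (truncated by the
#'   window), `value` (mean rate per year), `lower`, `upper`, `window`,
#'   and the per-row `rates` matrix. Cells where the density is zero are
#'   `NA`.
#' @export
kde_growth <- function(model, window = 25, on = c("ensemble", "mean")) {
  on <- match.arg(on)
  axis <- model$axis
  h <- window / axis$step
  if (h != round(h) || h < 1) stop("window must be a positive multiple of the axis step")
  h <- as.integer(h)
  G <- length(axis$bce)
  if (h >= G) stop("window longer than the axis")
  M <- if (on == "ensemble") model$ensemble else matrix(model$mean, nrow = 1)
  K0 <- M[, seq_len(G - h), drop = FALSE]
  K1 <- M[, (h + 1):G, drop = FALSE]
  rates <- (K1 / K0)^(1 / window) - 1
  rates[K0 == 0 | K1 == 0] <- NA_real_
  sub_axis <- cal_axis(axis$start_bce, axis$bce[G - h], axis$step)
  structure(
    list(axis = sub_axis,
         value = colMeans(rates, na.rm = TRUE),
         lower = apply(rates, 2, stats::quantile, 0.025, na.rm = TRUE),
         upper = apply(rates, 2, stats::quantile, 0.975, na.rm = TRUE),
         window = window, rates = rates),
    class = "growth_series"
  )
}

#' @export
print.growth_series <- function(x, ...) {
  cat(sprintf(
    "Growth-rate series (%d-yr window) on %d-%d BCE; mean rate %.4f%%/yr\n",
    x$window, as.integer(x$axis$start_bce), as.integer(x$axis$end_bce),
    100 * mean(x$value, na.rm = TRUE)
  ))
  invisible(x)
}

#' @export
as.data.frame.growth_series <- function(x, ...) {
  data.frame(year_bce = x$axis$bce, value = x$value,
             lower = x$lower, upper = x$upper)
}

#' Monte Carlo exponential-null test of an SPD
#'
#' Tests the observed summed probability distribution against a fitted
#' exponential growth model. The null `A * exp(lambda * t)` is fitted to
#' the observed SPD by least squares on the observation window; each of
#' `n_sim` simulations draws `n` calendar dates proportional to the
#' fitted model, attaches laboratory errors resampled from the observed
#' error set, forward-models them to radiocarbon ages
#' ([uncalibrate()]), recalibrates, and builds an SPD. The pointwise
#' 2.5/97.5-percentile simulation envelope flags deviation intervals
#' where the observed SPD exits it; the global p-value comes from the
#' summed exceedance of the z-scored SPD beyond the z-scored envelope,
#' compared with the same statistic on each simulation.
#'
#' @param dates canonical date table (>= 10 rows).
#' @param curve calibration curve.
#' @param axis calendar axis (observation window).
#' @param n_sim number of Monte Carlo simulations (default 200).
#' @param normalized normalized SPDs throughout (default TRUE).
#' @return Object of class `spd_nulltest`: observed and fitted values,
#'   simulation envelope, deviation `intervals` (data.frame with
#'   `start_bce`, `end_bce`, `sign`), `p_value`, fit coefficients.
#' @export
exp_null_test <- function(dates, curve, axis, n_sim = 200, normalized = TRUE) {
  if (nrow(dates) < 10) stop("exp_null_test needs at least 10 dates")
  obs <- spd(dates, curve, axis, normalized = normalized)
  t_fwd <- axis$start_bce - axis$bce # forward time from window start
  fit <- fit_exponential(t_fwd, obs$value)
  f <- fit$fitted
  n <- nrow(dates)
  S <- matrix(NA_real_, nrow = n_sim, ncol = length(axis$bce))
  for (r in seq_len(n_sim)) {
    yrs <- sample(axis$bce, n, replace = TRUE, prob = f)
    errs <- sample(dates$error, n, replace = TRUE)
    meas <- uncalibrate(yrs, curve, errs)
    P <- calibrate_matrix(meas$c14_age, meas$error, curve, axis,
                          normalized = normalized)
    S[r, ] <- rowSums(P) / axis$step
  }
  lo <- apply(S, 2, stats::quantile, 0.025)
  hi <- apply(S, 2, stats::quantile, 0.975)
  m <- colMeans(S)
  s <- apply(S, 2, stats::sd)
  s[s == 0] <- Inf # cells with no simulation variance carry no evidence
  zobs <- (obs$value - m) / s
  Z <- sweep(sweep(S, 2, m), 2, s, "/")
  zlo <- apply(Z, 2, stats::quantile, 0.025)
  zhi <- apply(Z, 2, stats::quantile, 0.975)
  exceed <- function(z) sum(pmax(0, z - zhi) + pmax(0, zlo - z))
  obs_stat <- exceed(zobs)
  sim_stat <- apply(Z, 1, exceed)
  p <- (1 + sum(sim_stat >= obs_stat)) / (1 + n_sim)
  outside <- ifelse(obs$value > hi, 1L, ifelse(obs$value < lo, -1L, 0L))
  structure(
    list(axis = axis, observed = obs$value, fitted = f,
         lower = lo, upper = hi, sim_mean = m,
         intervals = runs_to_intervals(axis$bce, outside, zobs),
         statistic = obs_stat, p_value = p, n_sim = n_sim,
         coef = c(A = fit$A, lambda = fit$lambda)),
    class = "spd_nulltest"
  )
}

# least-squares fit of A * exp(lambda * t); log-linear start values
fit_exponential <- function(t, v) {
  eps <- max(v) * 1e-9
  lmfit <- stats::lm(log(pmax(v, eps)) ~ t)
  start <- list(A = exp(stats::coef(lmfit)[[1]]), lambda = stats::coef(lmfit)[[2]])
  nl <- tryCatch(
    stats::nls(v ~ A * exp(lambda * t), start = start,
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL
  )
  if (is.null(nl)) stop("exponential null fit did not converge")
  co <- stats::coef(nl)
  list(A = co[["A"]], lambda = co[["lambda"]],
       fitted = co[["A"]] * exp(co[["lambda"]] * t))
}

# collapse a signed indicator vector over the axis into intervals
runs_to_intervals <- function(bce, outside, z = NULL) {
  r <- rle(outside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values != 0
  if (!any(keep)) {
    return(data.frame(start_bce = numeric(0), end_bce = numeric(0),
                      sign = character(0), peak_z = numeric(0)))
  }
  data.frame(
    start_bce = bce[starts[keep]],
    end_bce = bce[ends[keep]],
    sign = ifelse(r$values[keep] > 0, "positive", "negative"),
    peak_z = vapply(which(keep), function(k) {
      if (is.null(z)) return(NA_real_)
      seg <- z[starts[k]:ends[k]]
      seg[which.max(abs(seg))]
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.spd_nulltest <- function(x, ...) {
  cat("Monte Carlo exponential-null test of the SPD\n")
  cat(sprintf("  fitted null: A = %.4g, lambda = %.4g per yr; %d simulations\n",
              x$coef["A"], x$coef["lambda"], x$n_sim))
  cat(sprintf("  global p = %.4f (summed envelope exceedance = %.3f)\n",
              x$p_value, x$statistic))
  if (nrow(x$intervals) == 0) {
    cat("  no deviation intervals\n")
  } else {
    cat(sprintf("  %d deviation interval(s):\n", nrow(x$intervals)))
    for (i in seq_len(nrow(x$intervals))) {
      cat(sprintf("    %s: %d-%d BCE\n", x$intervals$sign[i],
                  as.integer(x$intervals$start_bce[i]),
                  as.integer(x$intervals$end_bce[i])))
    }
  }
  invisible(x)
}
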