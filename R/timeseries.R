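#' Coerce a proxy object to a plain time series data.frame
#'
#' All cross-proxy statistics operate on the common layout
#' `data.frame(year_bce, value)`. SPDs, KDE models, growth, aoristic and
#' openness series all coerce via their [as.data.frame()] methods; plain
#' data.frames pass through after a column check.
#'
#' @param x series-like object.
#' @return data.frame with `year_bce` and `value`.
#' @export
as_series <- function(x) {
  df <- as.data.frame(x)
  if (!all(c("year_bce", "value") %in% names(df))) {
    stop("cannot coerce to a series: need year_bce and value columns")
  }
  df
}

#' Detrend a time series
#'
#' Removes the underlying trend to expose the remaining variation:
#' subtracts the ordinary-least-squares line fitted over the analysis
#' window. The residual has mean zero by construction.
#'
#' @param series series-like object (>= 3 points).
#' @param method only `"linear"` is implemented.
#' @return data.frame `year_bce`, `value` (residuals).
#' @export
detrend <- function(series, method = "linear") {
  method <- match.arg(method, "linear")
  df <- as_series(series)
  df <- df[!is.na(df$value), , drop = FALSE]
  if (nrow(df) < 3) stop("detrend needs at least 3 points")
  fit <- stats::lm(value ~ year_bce, data = df)
  data.frame(year_bce = df$year_bce, value = stats::residuals(fit))
}

#' Bin a time series into fixed-width blocks
#'
#' Non-overlapping blocks of `width` years starting at the oldest year;
#' each bin is labelled by its midpoint and carries the block mean. A
#' trailing partial bin is dropped and reported via the `n_dropped`
#' attribute.
#'
#' @param series series-like object on a regular grid.
#' @param width block width in years (25 and 50 are the conventional
#'   choices).
#' @param stat summary statistic, default [mean()].
#' @return data.frame `year_bce` (bin midpoints), `value`; attribute
#'   `n_dropped` counts trailing points not covered by a full bin.
#' @export
bin_series <- function(series, width = 25, stat = mean) {
  df <- as_series(series)
  df <- df[order(-df$year_bce), , drop = FALSE]
  step <- unique(round(diff(-df$year_bce), 9))
  if (length(step) != 1) stop("bin_series needs a regular grid")
  per <- width / step
  if (per != round(per) || per < 1) stop("width must be a positive multiple of the grid step")
  per <- as.integer(per)
  n_bins <- nrow(df) %/% per
  n_drop <- nrow(df) - n_bins * per
  if (n_bins == 0) stop("series shorter than one bin")
  idx <- rep(seq_len(n_bins), each = per)
  used <- df[seq_len(n_bins * per), , drop = FALSE]
  out <- data.frame(
    year_bce = tapply(used$year_bce, idx, mean),
    value = tapply(used$value, idx, stat)
  )
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_drop
  out
}

#' Windowed Pearson correlation between two proxies
#'
#' Pearson product-moment correlation of two series over a calendar
#' window, after aligning them on common years. The canonical windows are
#' the full observation period (2850--1700 BCE) and its two cultural
#' phases, MNB (2850--2350 BCE) and LN (2350--1700 BCE).
#'
#' @param a,b series-like objects sharing grid years inside the window.
#' @param window `c(oldest, youngest)` years BCE; `NULL` uses the full
#'   overlap.
#' @return Pearson r.
#' @export
window_pearson <- function(a, b, window = NULL) {
  da <- as_series(a); db <- as_series(b)
  m <- merge(da, db, by = "year_bce", suffixes = c("_a", "_b"))
  if (!is.null(window)) {
    m <- m[m$year_bce <= window[1] & m$year_bce >= window[2], , drop = FALSE]
  }
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) stop("fewer than 3 aligned points in the window")
  if (stats::sd(m$value_a) == 0 || stats::sd(m$value_b) == 0) {
    stop("undefined correlation: a series has zero variance in the window")
  }
  stats::cor(m$value_a, m$value_b)
}

#' Lagged cross-correlation between two proxies
#'
#' Pearson correlation at integer-bin lags from `-max_lag` to `+max_lag`
#' years. Positive lag means `a` leads `b`: the correlation pairs `a` at
#' time t with `b` lag years later (closer to the present). Lags leaving
#' fewer than 3 overlapping points are skipped.
#'
#' @param a,b series-like objects on identical regular grids.
#' @param max_lag maximum lag in years (multiple of the grid step).
#' @return Object of class `xcorr`: data.frame `lag` (years), `r`;
#'   attributes `best_lag` and `best_r` at max |r|.
#' @export
cross_correlation <- function(a, b, max_lag) {
  da <- as_series(a); db <- as_series(b)
  da <- da[order(-da$year_bce), ]; db <- db[order(-db$year_bce), ]
  if (nrow(da) != nrow(db) || any(da$year_bce != db$year_bce)) {
    stop("series must share an identical axis")
  }
  step <- unique(round(diff(-da$year_bce), 9))
  if (length(step) != 1) stop("cross_correlation needs a regular grid")
  L <- max_lag / step
  if (L != round(L) || L < 0) stop("max_lag must be a non-negative multiple of the grid step")
  L <- as.integer(L)
  n <- nrow(da)
  x <- da$value; y <- db$value
  rows <- list()
  for (k in -L:L) {
    if (k >= 0) {
      xi <- seq_len(n - k); yi <- xi + k
    } else {
      yi <- seq_len(n + k); xi <- yi - k
    }
    ok <- stats::complete.cases(x[xi], y[yi])
    if (sum(ok) < 3) next
    if (stats::sd(x[xi][ok]) == 0 || stats::sd(y[yi][ok]) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      lag = k * step, r = stats::cor(x[xi][ok], y[yi][ok])
    )
  }
  if (length(rows) == 0) stop("no lag admits 3 overlapping points")
  out <- do.call(rbind, rows)
  best <- which.max(abs(out$r))
  attr(out, "best_lag") <- out$lag[best]
  attr(out, "best_r") <- out$r[best]
  class(out) <- c("xcorr", "data.frame")
  out
}

#' @export
print.xcorr <- function(x, ...) {
  cat(sprintf("Cross-correlation over lags %d..%d yr; max |r| = %.3f at lag %+d yr\n",
              min(x$lag), max(x$lag), attr(x, "best_r"), attr(x, "best_lag")))
  invisible(x)
}

#' Autocorrelation of a proxy series
#'
#' The cross-correlation of a series with itself: similarity between the
#' series and lagged versions of it.
#'
#' @inheritParams cross_correlation
#' @param a series-like object.
#' @return `xcorr` object (see [cross_correlation()]).
#' @export
autocorrelation <- function(a, max_lag) {
  cross_correlation(a, a, max_lag)
}

#' SD-threshold event detection
#'
#' Flags 'significant' anomalies in a (detrended or growth-rate) series:
#' the series is z-scored against its own mean and standard deviation
#' over the analysis window, and maximal runs with `|z| >= k` become
#' events, signed by the direction of the excursion. The standard
#' deviation is used as the threshold statistic because smoothed series
#' (e.g. KDE models) have little pronounced variance.
#'
#' When `lower`/`upper` envelope columns are present (KDE-derived series)
#' and `require_envelope = TRUE`, an event is only flagged where the
#' whole envelope crosses the threshold — a stricter notion of
#' significance.
#'
#' @param series series-like object; `lower`/`upper` columns are used in
#'   envelope mode.
#' @param k threshold in standard-deviation multiples (default 1).
#' @param basis `"none"` uses the series as supplied (appropriate for
#'   growth rates); `"detrended"` removes a linear trend first.
#' @param require_envelope stricter envelope-crossing mode (default FALSE).
#' @return Object of class `event_set`: data.frame `start_bce`,
#'   `end_bce`, `sign`, `peak_z`; attributes `k`, `mean`, `sd`.
#' @export
detect_events <- function(series, k = 1, basis = c("none", "detrended"),
                          require_envelope = FALSE) {
  basis <- match.arg(basis)
  raw <- as.data.frame(series)
  df <- if (basis == "detrended") detrend(series) else as_series(series)
  ok <- !is.na(df$value)
  mu <- mean(df$value[ok])
  sdv <- stats::sd(df$value[ok])
  if (is.na(sdv) || sdv == 0) stop("degenerate series: zero standard deviation")
  z <- (df$value - mu) / sdv
  outside <- ifelse(!is.na(z) & z >= k, 1L, ifelse(!is.na(z) & z <= -k, -1L, 0L))
  if (require_envelope) {
    if (!all(c("lower", "upper") %in% names(raw))) {
      stop("require_envelope = TRUE needs lower/upper columns in the series")
    }
    zlo <- (raw$lower - mu) / sdv
    zhi <- (raw$upper - mu) / sdv
    outside[outside == 1L & !(zlo >= k)] <- 0L
    outside[outside == -1L & !(zhi <= -k)] <- 0L
  }
  ev <- runs_to_intervals(df$year_bce, outside, z)
  structure(ev, class = c("event_set", "data.frame"),
            k = k, mean = mu, sd = sdv)
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("Event set (threshold %g SD): %d event(s)\n", attr(x, "k"), nrow(x)))
  if (nrow(x) > 0) {
    for (i in seq_len(nrow(x))) {
      cat(sprintf("  %s %d-%d BCE (peak z %+.2f)\n", x$sign[i],
                  as.integer(x$start_bce[i]), as.integer(x$end_bce[i]),
                  x$peak_z[i]))
    }
  }
  invisible(x)
}
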