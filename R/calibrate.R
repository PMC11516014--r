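#' Calibrate a single radiocarbon determination
#'
#' Converts a laboratory measurement `d +/- sigma` (14C yr BP) into a
#' probability distribution over calendar years. For each grid year theta
#' the likelihood is the Gaussian
#' \deqn{L(\theta) = \frac{1}{\sqrt{2\pi(\sigma^2+\sigma_c(\theta)^2)}}
#'   \exp\!\left(-\frac{(d-\mu(\theta))^2}{2(\sigma^2+\sigma_c(\theta)^2)}\right)}
#' where `mu` and `sigma_c` are the calibration curve and its error,
#' interpolated linearly between knots. In normalized mode the result is
#' rescaled to sum to one over the axis; in unnormalized mode the raw
#' likelihood heights times the grid step are returned (the two modes
#' correspond to normalised and non-normalised summed probability
#' distributions).
#'
#' Densities are always renormalized over the axis; when more than 0.1%
#' of the untruncated mass falls outside it a truncation warning is
#' issued (windows are normally padded by 100 years to avoid such
#' boundary effects).
#'
#' @param c14_age measured radiocarbon age d (14C yr BP), or a list /
#'   one-row data.frame with fields `c14_age` and `error`.
#' @param error laboratory 1-sigma error (14C yr); ignored when
#'   `c14_age` carries both fields.
#' @param curve a [cal_curve][read_calcurve] object.
#' @param axis a [cal_axis()] inside the curve's coverage.
#' @param normalized logical; default TRUE.
#' @return Object of class `cal_density`: list with `axis`, `mass`
#'   (probability per grid cell; sums to 1 when normalized),
#'   `normalized`, and `truncated_mass` (fraction cut by the axis).
#' @export
calibrate <- function(c14_age, error = NULL, curve, axis, normalized = TRUE) {
  if (is.list(c14_age)) {
    error <- c14_age$error[1]
    c14_age <- c14_age$c14_age[1]
  }
  if (is.null(error) || is.na(error) || error <= 0) {
    stop("error must be a positive 14C-year 1-sigma value")
  }
  if (!curve_covers(curve, axis)) stop("axis extends outside calibration curve coverage")
  th <- axis_calbp(axis)
  cv <- curve_at(curve, th)
  s2 <- error^2 + cv$sigma^2
  L <- stats::dnorm(c14_age, mean = cv$mu, sd = sqrt(s2))
  tot <- sum(L)
  if (tot <= 0) stop("degenerate density: zero likelihood everywhere on axis")
  trunc_frac <- truncated_fraction(c14_age, error, curve, axis, tot)
  if (trunc_frac > 1e-3) {
    warning(sprintf("%.2f%% of untruncated calibrated mass falls outside the axis",
                    100 * trunc_frac))
  }
  mass <- if (normalized) L / tot else L * axis$step
  structure(
    list(axis = axis, mass = mass, normalized = normalized,
         truncated_mass = trunc_frac),
    class = "cal_density"
  )
}

# Fraction of calibrated mass cut by the axis, estimated on an annual grid
# extended 10 total-sigma beyond the axis (clipped to curve coverage). Mass
# mapped to calendar regions further away than that is treated as
# negligible for the truncation diagnostic.
truncated_fraction <- function(c14_age, error, curve, axis, inside_sum) {
  pad <- 10 * sqrt(error^2 + max(curve$sigma_curve)^2)
  th <- axis_calbp(axis)
  lo <- max(min(curve$theta), min(th) - pad)
  hi <- min(max(curve$theta), max(th) + pad)
  grid <- seq(lo, hi, by = axis$step)
  cv <- curve_at(curve, grid)
  L <- stats::dnorm(c14_age, mean = cv$mu, sd = sqrt(error^2 + cv$sigma^2))
  total <- sum(L)
  if (total <= 0) return(0)
  max(0, 1 - inside_sum / total)
}

# Vectorised calibration of many determinations on a shared axis.
# Returns a (grid x n) matrix; columns are normalized to unit sum when
# normalized = TRUE, else raw likelihood * step. Hot path for SPDs,
# composite KDE models and the Monte Carlo null test.
calibrate_matrix <- function(c14_age, error, curve, axis, normalized = TRUE) {
  if (any(error <= 0)) stop("all errors must be positive")
  if (!curve_covers(curve, axis)) stop("axis extends outside calibration curve coverage")
  th <- axis_calbp(axis)
  cv <- curve_at(curve, th)
  G <- length(th); n <- length(c14_age)
  s2 <- outer(cv$sigma^2, error^2, "+")
  D <- matrix(c14_age, nrow = G, ncol = n, byrow = TRUE)
  L <- stats::dnorm(D, mean = cv$mu, sd = sqrt(s2))
  if (normalized) {
    tot <- colSums(L)
    if (any(tot <= 0)) stop("degenerate density for at least one date")
    sweep(L, 2, tot, "/")
  } else {
    L * axis$step
  }
}

#' @export
print.cal_density <- function(x, ...) {
  md <- x$axis$bce[which.max(x$mass)]
  cat(sprintf(
    "Calibrated density on %d-%d BCE (step %d): mode %d BCE, %s%s\n",
    as.integer(x$axis$start_bce), as.integer(x$axis$end_bce),
    as.integer(x$axis$step), as.integer(md),
    if (x$normalized) "normalized" else "unnormalized",
    if (x$truncated_mass > 1e-3)
      sprintf(" (%.2f%% mass truncated)", 100 * x$truncated_mass) else ""
  ))
  invisible(x)
}

#' @export
as.data.frame.cal_density <- function(x, ...) {
  data.frame(year_bce = x$axis$bce, value = x$mass)
}

#' Sample calendar years from a calibrated density
#'
#' Draws calendar years (BCE) with probability proportional to the
#' density's per-cell mass. Reproducible under a fixed RNG seed.
#'
#' @param density a normalized `cal_density`.
#' @param n number of draws.
#' @return integer-valued vector of years BCE.
#' @export
sample_calendar_year <- function(density, n = 1) {
  if (!density$normalized) stop("density must be normalized for sampling")
  if (sum(density$mass) <= 0) stop("degenerate density: all-zero mass")
  if (length(density$axis$bce) == 1) {
    return(rep(density$axis$bce, n))
  }
  sample(density$axis$bce, size = n, replace = TRUE, prob = density$mass)
}

#' Forward-model a calendar year to a radiocarbon measurement
#'
#' The inverse of calibration, used by the synthetic generator and the
#' Monte Carlo null test: for a true calendar year the measured age is
#' drawn from `Normal(mu(theta), sqrt(lab_error^2 + sigma_c(theta)^2))`
#' at `theta = bce_to_calbp(true_year)`.
#'
#' @param true_year_bce true calendar year(s), years BCE.
#' @param curve calibration curve covering the year(s).
#' @param lab_error reported laboratory error(s) (14C yr), > 0; recycled.
#' @return data.frame with columns `c14_age` (rounded to whole 14C years)
#'   and `error`.
#' @export
uncalibrate <- function(true_year_bce, curve, lab_error) {
  if (any(lab_error <= 0)) stop("lab_error must be positive")
  n <- length(true_year_bce)
  lab_error <- rep_len(lab_error, n)
  th <- bce_to_calbp(true_year_bce)
  if (any(th < min(curve$theta) | th > max(curve$theta))) {
    stop("true year outside calibration curve coverage")
  }
  cv <- curve_at(curve, th)
  age <- stats::rnorm(n, mean = cv$mu, sd = sqrt(lab_error^2 + cv$sigma^2))
  data.frame(c14_age = round(age), error = lab_error)
}
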