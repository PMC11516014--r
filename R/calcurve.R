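#' Read a radiocarbon calibration curve
#'
#' Reads a calibration curve mapping calendar age theta (cal BP) to the
#' expected radiocarbon age `mu(theta)` with its one-sigma curve error
#' `sigma_curve(theta)`. Two dialects are supported: the standard IntCal
#' `.14c` layout (comment lines starting with `#`, then comma-separated
#' columns CAL BP, 14C age, Error; further columns ignored) and a plain
#' CSV with a header naming columns `calbp`, `c14age`, `error`.
#'
#' Knots are sorted by ascending theta; between knots both `mu` and
#' `sigma_curve` are interpolated linearly.
#'
#' @param path path to the curve file.
#' @param dialect `"intcal14c"` or `"plain_csv"`.
#' @return Object of class `cal_curve`: list with numeric vectors `theta`
#'   (cal BP, ascending), `mu`, `sigma_curve`.
#' @export
read_calcurve <- function(path, dialect = c("intcal14c", "plain_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("calibration curve file not found: ", path)
  if (dialect == "intcal14c") {
    lines <- readLines(path)
    keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
    idx <- which(keep)
    if (length(idx) == 0) stop("no data rows in calibration curve file")
    parts <- strsplit(lines[idx], ",")
    rows <- lapply(seq_along(parts), function(i) {
      p <- trimws(parts[[i]])
      if (length(p) < 3) {
        stop(sprintf("malformed calibration curve row at line %d: fewer than 3 fields", idx[i]))
      }
      v <- suppressWarnings(as.numeric(p[1:3]))
      if (anyNA(v)) {
        stop(sprintf("malformed calibration curve row at line %d: non-numeric field", idx[i]))
      }
      v
    })
    m <- do.call(rbind, rows)
    theta <- m[, 1]; mu <- m[, 2]; sig <- m[, 3]
  } else {
    df <- utils::read.csv(path, comment.char = "#")
    names(df) <- tolower(names(df))
    need <- c("calbp", "c14age", "error")
    if (!all(need %in% names(df))) {
      stop("plain_csv curve needs columns: ", paste(need, collapse = ", "))
    }
    theta <- as.numeric(df$calbp); mu <- as.numeric(df$c14age); sig <- as.numeric(df$error)
    if (anyNA(theta) || anyNA(mu) || anyNA(sig)) stop("non-numeric value in curve columns")
  }
  new_calcurve(theta, mu, sig)
}

#' Construct a calibration curve from knot vectors
#'
#' @param theta calendar ages of the knots (cal BP).
#' @param mu expected radiocarbon age at each knot (14C yr BP).
#' @param sigma_curve one-sigma curve error at each knot (14C yr), >= 0.
#' @return A `cal_curve` object with knots sorted by ascending `theta`.
#' @export
new_calcurve <- function(theta, mu, sigma_curve) {
  if (length(theta) < 2) stop("calibration curve needs at least 2 knots")
  if (anyDuplicated(theta)) stop("duplicate theta knots in calibration curve")
  if (any(sigma_curve < 0)) stop("sigma_curve must be >= 0")
  o <- order(theta)
  structure(
    list(theta = as.numeric(theta[o]), mu = as.numeric(mu[o]),
         sigma_curve = as.numeric(sigma_curve[o])),
    class = "cal_curve"
  )
}

#' @export
print.cal_curve <- function(x, ...) {
  cat(sprintf(
    "Calibration curve: %d knots, %s-%s cal BP, mu range %s-%s 14C BP\n",
    length(x$theta), format(min(x$theta)), format(max(x$theta)),
    format(round(min(x$mu))), format(round(max(x$mu)))
  ))
  invisible(x)
}

# linear interpolation of mu and sigma_curve at arbitrary theta (cal BP)
curve_at <- function(curve, theta) {
  if (any(theta < min(curve$theta) | theta > max(curve$theta))) {
    stop("requested theta outside calibration curve coverage")
  }
  list(
    mu = stats::approx(curve$theta, curve$mu, xout = theta)$y,
    sigma = stats::approx(curve$theta, curve$sigma_curve, xout = theta)$y
  )
}

# does the curve cover this axis entirely?
curve_covers <- function(curve, axis) {
  th <- axis_calbp(axis)
  min(th) >= min(curve$theta) && max(th) <= max(curve$theta)
}

#' Synthetic calibration curve for simulation and testing
#'
#' Builds a curve whose expected radiocarbon age is the identity
#' (`mu(theta) = theta`) optionally distorted by a sinusoidal wiggle and a
#' flat plateau segment. Plateaus in real curves (e.g. the stretch around
#' 2450--2200 BCE) spread calibrated probability over wide calendar
#' intervals and can mimic or mask demographic events; this generator lets
#' that artefact be reproduced on demand.
#'
#' @param theta_min,theta_max curve coverage in cal BP.
#' @param knot_step knot spacing in years (default 5, matching the
#'   published spacing of modern curves in this era).
#' @param sigma_curve constant curve error (14C yr), default 10.
#' @param wiggle_amp amplitude of the sinusoidal wiggle (14C yr), default 0.
#' @param wiggle_period period of the wiggle (yr), default 500.
#' @param plateau optional `c(start, end)` in cal BP: within this segment
#'   `mu` is held constant at its value at the segment start.
#' @return A `cal_curve`.
#' @examples
#' cc <- synthetic_calcurve(3000, 5500, wiggle_amp = 20)
#' @export
synthetic_calcurve <- function(theta_min, theta_max, knot_step = 5,
                               sigma_curve = 10, wiggle_amp = 0,
                               wiggle_period = 500, plateau = NULL) {
  theta <- seq(theta_min, theta_max, by = knot_step)
  mu <- theta + wiggle_amp * sin(2 * pi * theta / wiggle_period)
  if (!is.null(plateau)) {
    lo <- min(plateau); hi <- max(plateau)
    inside <- theta >= lo & theta <= hi
    if (any(inside)) mu[inside] <- mu[which(inside)[1]]
  }
  new_calcurve(theta, mu, rep(sigma_curve, length(theta)))
}
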