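#' Calendar axis for proxy time series
#'
#' All series in the package live on a shared annual (or coarser) calendar
#' grid expressed in years BCE, counting down toward the present
#' (`start_bce > end_bce`). The package-wide convention for converting to
#' the radiocarbon community's cal BP scale is `cal BP = BCE + 1949`,
#' i.e. 1 BCE corresponds to 1950 cal BP (there is no year zero).
#'
#' @param start_bce oldest year of the grid (years BCE).
#' @param end_bce youngest year of the grid (years BCE); must be smaller
#'   than `start_bce`.
#' @param step grid spacing in years (default 1).
#' @return An object of class `cal_axis`: a list with fields `start_bce`,
#'   `end_bce`, `step` and the materialised grid `bce` (descending).
#' @examples
#' ax <- cal_axis(2950, 1600)
#' length(ax$bce)
#' @export
cal_axis <- function(start_bce, end_bce, step = 1L) {
  start_bce <- as.numeric(start_bce)
  end_bce <- as.numeric(end_bce)
  step <- as.numeric(step)
  if (!(start_bce > end_bce)) {
    stop("start_bce must be greater than end_bce (BCE counts down toward the present)")
  }
  if (step < 1) stop("step must be >= 1 year")
  if ((start_bce - end_bce) %% step != 0) {
    stop("(start_bce - end_bce) must be a multiple of step")
  }
  structure(
    list(
      start_bce = start_bce,
      end_bce = end_bce,
      step = step,
      bce = seq(start_bce, end_bce, by = -step)
    ),
    class = "cal_axis"
  )
}

#' @export
print.cal_axis <- function(x, ...) {
  cat(sprintf(
    "Calendar axis: %d-%d BCE, step %d yr (%d cells)\n",
    as.integer(x$start_bce), as.integer(x$end_bce),
    as.integer(x$step), length(x$bce)
  ))
  invisible(x)
}

#' @export
length.cal_axis <- function(x) length(x$bce)

#' Convert between years BCE and cal BP
#'
#' Uses the declared convention cal BP = BCE + 1949, which maps 1 BCE to
#' 1950 cal BP. The conversion is an exact, strictly increasing bijection.
#'
#' @param year_bce year(s) BCE; must be >= 1.
#' @param calbp calendar year(s) BP; must be >= 1950.
#' @return Numeric vector of converted years.
#' @examples
#' bce_to_calbp(2050) # 3999
#' calbp_to_bce(1950) # 1
#' @export
bce_to_calbp <- function(year_bce) {
  if (any(year_bce < 1)) stop("year_bce must be >= 1 (no year zero)")
  year_bce + 1949
}

#' @rdname bce_to_calbp
#' @export
calbp_to_bce <- function(calbp) {
  if (any(calbp < 1950)) stop("calbp must be >= 1950 to map into BCE")
  calbp - 1949
}

# cal BP grid of an axis (ascending in BCE means ascending in BP too)
axis_calbp <- function(axis) bce_to_calbp(axis$bce)

# check two axes are identical grids
same_axis <- function(a, b) {
  isTRUE(all.equal(a$start_bce, b$start_bce)) &&
    isTRUE(all.equal(a$end_bce, b$end_bce)) &&
    isTRUE(all.equal(a$step, b$step))
}
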