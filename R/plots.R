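# Base-graphics plot methods. All proxy plots share the reversed BCE
# x-axis (older years left) and optional event-interval shading.

plot_bce_frame <- function(bce, ylim, ylab, main) {
  plot(NA, xlim = rev(range(bce)), ylim = ylim, xlab = "year BCE",
       ylab = ylab, main = main)
}

shade_events <- function(events, ylim) {
  if (is.null(events) || nrow(events) == 0) return(invisible(NULL))
  for (i in seq_len(nrow(events))) {
    col <- if (events$sign[i] == "positive") grDevices::rgb(1, 0, 0, 0.15)
           else grDevices::rgb(0, 0, 1, 0.15)
    graphics::rect(events$start_bce[i], ylim[1], events$end_bce[i], ylim[2],
                   col = col, border = NA)
  }
}

#' @export
plot.spd_series <- function(x, main = "Summed probability distribution", ...) {
  plot_bce_frame(x$axis$bce, c(0, max(x$value) * 1.05),
                 "summed probability / yr", main)
  graphics::lines(x$axis$bce, x$value, ...)
  invisible(x)
}

#' @export
plot.ckde_model <- function(x, events = NULL,
                            main = "Composite KDE model", ...) {
  ylim <- c(0, max(x$upper) * 1.05)
  plot_bce_frame(x$axis$bce, ylim, "density / yr", main)
  shade_events(events, ylim)
  graphics::polygon(c(x$axis$bce, rev(x$axis$bce)), c(x$lower, rev(x$upper)),
                    col = "grey85", border = NA)
  graphics::lines(x$axis$bce, x$mean, ...)
  invisible(x)
}

#' @export
plot.growth_series <- function(x, events = NULL,
                               main = "KDE growth rate", ...) {
  ylim <- range(c(x$lower, x$upper), na.rm = TRUE)
  plot_bce_frame(x$axis$bce, ylim, "growth rate / yr", main)
  shade_events(events, ylim)
  graphics::polygon(c(x$axis$bce, rev(x$axis$bce)), c(x$lower, rev(x$upper)),
                    col = "grey85", border = NA)
  graphics::lines(x$axis$bce, x$value, ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' @export
plot.spd_nulltest <- function(x, main = "SPD vs exponential null", ...) {
  ylim <- c(0, max(c(x$observed, x$upper)) * 1.05)
  plot_bce_frame(x$axis$bce, ylim, "summed probability / yr", main)
  shade_events(x$intervals, ylim)
  graphics::polygon(c(x$axis$bce, rev(x$axis$bce)), c(x$lower, rev(x$upper)),
                    col = "grey85", border = NA)
  graphics::lines(x$axis$bce, x$fitted, lty = 2)
  graphics::lines(x$axis$bce, x$observed, ...)
  graphics::mtext(sprintf("global p = %.3f", x$p_value), side = 3, cex = 0.8)
  invisible(x)
}

#' @export
plot.aoristic_series <- function(x, main = "Aoristic sum", ...) {
  plot_bce_frame(x$axis$bce, c(0, max(x$value) * 1.05),
                 "aoristic weight / yr", main)
  graphics::lines(x$axis$bce, x$value, ...)
  invisible(x)
}

#' @export
plot.openness_series <- function(x, events = NULL,
                                 main = "Vegetation openness score", ...) {
  ylim <- range(x$value, na.rm = TRUE)
  plot_bce_frame(x$axis$bce, ylim, "openness score (PC1)", main)
  shade_events(events, ylim)
  graphics::lines(x$axis$bce, x$value, ...)
  invisible(x)
}

#' @export
plot.pop_trajectory <- function(x, main = "Population trajectory", ...) {
  plot_bce_frame(x$axis$bce, c(0, max(x$density) * 1.05),
                 "relative density", main)
  graphics::lines(x$axis$bce, x$density, ...)
  invisible(x)
}
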