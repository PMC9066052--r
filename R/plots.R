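# Small base-graphics helpers for the main outputs.

#' @export
plot.volume_trace <- function(x, call = NULL, ...) {
  t_min <- (seq_along(x$volume_um3) - 1) * x$frame_interval
  graphics::plot(t_min, x$volume_um3, type = "l", xlab = "time (min)",
                 ylab = expression("ER volume (" * mu * m^3 * ")"), ...)
  if (!is.null(call)) graphics::abline(v = call$time_min, lty = 2, col = "red")
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  graphics::plot(x$fit, conf.int = FALSE, mark.time = TRUE,
                 xlab = "time (min)", ylab = "fraction not congressed", ...)
  invisible(x)
}

#' Plot pooled canonical kinetochore positions
#'
#' xy projection of [register_canonical()] output, coloured by class
#' (aligned grey, free orange, ensheathed red, poles black).
#' @param pooled data.frame from [register_canonical()].
#' @param ... passed to plot().
#' @export
plot_canonical <- function(pooled, ...) {
  cols <- c(aligned = "grey50", free = "darkorange", ensheathed = "red3", pole = "black")
  graphics::plot(pooled$x, pooled$y, col = cols[pooled$class],
                 pch = ifelse(pooled$class == "pole", 17, 16),
                 xlab = "x (µm, spindle axis)", ylab = "y (µm)", asp = 1, ...)
  invisible(pooled)
}
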