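.catchment_circle <- function(center, radius, ...) {
  th <- seq(0, 2 * pi, length.out = 72)
  graphics::lines(center[1] + radius * cos(th),
                  center[2] + radius * sin(th), ...)
}

#' Plot a trajectory over its world
#'
#' Draws the path (outbound steps red, inbound steps blue, undecided
#' grey), the nest and food catchments, and all landmark catchment
#' circles (route landmarks red/blue by gating direction, place
#' landmarks yellow/green), in the style of an annotated top-down map.
#'
#' @param log an `antnav_log`.
#' @param sc the [scenario()] it was run under (for world geometry);
#'   omit to plot the bare path.
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly `NULL`.
#' @export
plot_trajectory <- function(log, sc = NULL, ...) {
  stopifnot(is.data.frame(log))
  xr <- range(log$x); yr <- range(log$y)
  if (!is.null(sc)) {
    pts <- rbind(sc$nest, t(vapply(sc$food, function(f) f$pos,
                                   numeric(2))))
    xr <- range(xr, pts[, 1]); yr <- range(yr, pts[, 2])
  }
  graphics::plot(NA, xlim = xr + c(-40, 40), ylim = yr + c(-40, 40),
                 asp = 1, xlab = "x (length units)",
                 ylab = "y (length units)", ...)
  if (!is.null(sc)) {
    .catchment_circle(sc$nest, sc$eps_goal, col = "goldenrod", lwd = 2)
    for (f in sc$food)
      .catchment_circle(f$pos, sc$eps_goal, col = "darkgreen", lwd = 2)
    for (el in sc$landmarks) {
      if (el$kind == "route")
        .catchment_circle(el$center, el$radius,
                          col = ifelse(el$gate_direction == "outbound",
                                       "red", "blue"), lty = 2)
      else
        .catchment_circle(el$goal, el$radius,
                          col = ifelse(el$gate_direction == "inbound",
                                       "goldenrod", "darkgreen"), lty = 3)
    }
  }
  cols <- c(outbound = "red", inbound = "blue", none = "grey50")
  graphics::points(log$x, log$y, pch = 15, cex = 0.5,
                   col = cols[log$leg])
  invisible(NULL)
}

#' @export
plot.search_profile <- function(x, ...) {
  graphics::barplot(x$density, names.arg = round(x$mid),
                    xlab = "distance from origin (length units)",
                    ylab = "visit density",
                    main = sprintf("search density profile (n = %d paths)",
                                   attr(x, "n_paths")), ...)
  invisible(x)
}

#' @export
plot.distance_series <- function(x, ...) {
  graphics::plot(x$step, x$distance, type = "l",
                 xlab = "step", ylab = "distance to origin", ...)
  invisible(x)
}
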