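#' Distance-to-origin time series of a trajectory
#'
#' For a zero-vector search the distance to the release point equals the
#' current-vector length, so this series is the standard summary of how a
#' search unfolds in time: an oscillating curve whose envelope grows as
#' the searched area widens.
#'
#' @param log an `antnav_log` from [run_scenario()].
#' @param origin reference position `c(x, y)`.
#' @return a data.frame of class `distance_series` with columns `step`,
#'   `distance`.
#' @export
distance_series <- function(log, origin) {
  stopifnot(is.data.frame(log), nrow(log) >= 1L, length(origin) == 2L)
  d <- sqrt((log$x - origin[1])^2 + (log$y - origin[2])^2)
  structure(data.frame(step = log$step, distance = d),
            class = c("distance_series", "data.frame"))
}

#' Radial density profile of search paths
#'
#' Bins the per-step distances from the origin into radial shells,
#' normalizes each path's histogram to proportions, and averages across
#' paths: where the agent spends its searching time. Two normalizations
#' are reported: `prop`, the mean proportion of steps falling into each
#' radial bin, and `density`, the proportion divided by the area of the
#' bin's annulus and renormalized — occupancy per unit ground area, the
#' quantity search-density profiles of real foragers are plotted in. For
#' an emergent area-concentrated search the `density` profile is
#' unimodal and peaked at the origin.
#'
#' @param logs a single `antnav_log` or a list of them.
#' @param origin search origin `c(x, y)`.
#' @param bin_width radial bin width in length units (default 10, one
#'   step).
#' @return a data.frame of class `search_profile` with columns `bin_lo`,
#'   `bin_hi`, `mid`, `prop`, `density` (both non-negative, each summing
#'   to 1), and attribute `n_paths`.
#' @export
density_profile <- function(logs, origin, bin_width = 10) {
  if (is.data.frame(logs)) logs <- list(logs)
  stopifnot(length(logs) >= 1L, bin_width > 0)
  dists <- lapply(logs, function(l) distance_series(l, origin)$distance)
  max_d <- max(unlist(dists))
  breaks <- seq(0, max_d + bin_width, by = bin_width)
  prop <- vapply(dists, function(d) {
    h <- graphics::hist(d, breaks = breaks, plot = FALSE)
    h$counts / sum(h$counts)
  }, numeric(length(breaks) - 1L))
  prop <- if (is.matrix(prop)) rowMeans(prop) else prop
  prop <- prop / sum(prop)
  area <- pi * (breaks[-1L]^2 - breaks[-length(breaks)]^2)
  dens <- prop / area
  dens <- dens / sum(dens)
  structure(data.frame(bin_lo = breaks[-length(breaks)],
                       bin_hi = breaks[-1L],
                       mid = (breaks[-1L] + breaks[-length(breaks)]) / 2,
                       prop = prop, density = dens),
            class = c("search_profile", "data.frame"),
            n_paths = length(logs), bin_width = bin_width)
}

#' Run a scenario under several seeds
#'
#' Independent replicate runs, one per seed; results for a given seed do
#' not depend on the order or presence of the other seeds.
#'
#' @param sc an [scenario()].
#' @param seeds vector of distinct integer seeds.
#' @return a list of `antnav_log` objects, one per seed, in seed order.
#' @export
batch_run <- function(sc, seeds) {
  stopifnot(!anyDuplicated(seeds))
  lapply(seeds, function(s) run_scenario(sc, seed = s))
}
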