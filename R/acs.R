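#' Default parameters of the search subsystem
#'
#' The area-concentrated search generator is parameterized by the bounds of
#' its uniform turn distribution and by the two distance breakpoints of the
#' gain function [acs_gain()], together with their time-dependent maxima.
#'
#' @param turn_min,turn_max bounds of the per-step heading change (radians);
#'   the asymmetric default interval biases towards counter-clockwise
#'   turns (mean +0.2 rad).
#' @param d1_0,d2_0 breakpoints at search onset: full gain below `d1_0`
#'   (3.3 length units), zero gain beyond `d2_0` (20 units).
#' @param d1_max,d2_max breakpoint values after long searching (33 and 200
#'   units): the searched area widens with time.
#' @param t_max searching time (steps) at which both breakpoints reach
#'   their maxima; they interpolate linearly on the way.
#' @return a list of class `acs_config`.
#' @export
acs_config <- function(turn_min = -0.3, turn_max = 0.7,
                       d1_0 = 3.3, d2_0 = 20,
                       d1_max = 33, d2_max = 200,
                       t_max = 500) {
  stopifnot(turn_min < turn_max, d1_0 < d2_0, d1_max < d2_max,
            d1_0 <= d1_max, d2_0 <= d2_max, t_max > 0)
  structure(list(turn_min = turn_min, turn_max = turn_max,
                 d1_0 = d1_0, d2_0 = d2_0,
                 d1_max = d1_max, d2_max = d2_max, t_max = t_max),
            class = "acs_config")
}

#' Draw a random heading change
#'
#' Uniform on `[turn_min, turn_max]` (default `[-0.3, 0.7]` rad, mean
#' +0.2): successive turns share a counter-clockwise bias, so a free-running
#' agent tends to walk in loops rather than straight lines.
#'
#' @param rng an [rng_stream()].
#' @param config an [acs_config()].
#' @return a heading change in radians.
#' @export
draw_turn <- function(rng, config = acs_config()) {
  rng_uniform(rng, 1L, min = config$turn_min, max = config$turn_max)
}

#' Search gain as a function of goal distance and searching time
#'
#' The gain is 1 while the path integrator reports a goal distance below
#' the inner breakpoint `d1(t)`, falls linearly to 0 at the outer
#' breakpoint `d2(t)`, and is 0 beyond. Both breakpoints start at (3.3, 20)
#' length units and grow linearly with searching time until they saturate
#' at (33, 200) after `t_max` steps, emulating the widening of the search
#' with unsuccessful searching time.
#'
#' @param d goal distance reported by the path integrator (length of the
#'   difference between gated reference and current vector; for an inbound
#'   agent this is simply the current-vector length). Non-negative.
#' @param t searching time in steps since search onset. Non-negative.
#' @param config an [acs_config()].
#' @return gain in `[0, 1]`; vectorized over `d` and `t`.
#' @export
#' @examples
#' acs_gain(2, 0)    # 1
#' acs_gain(20, 0)   # 0
acs_gain <- function(d, t, config = acs_config()) {
  stopifnot(all(d >= 0), all(t >= 0))
  frac <- pmin(t / config$t_max, 1)
  d1 <- config$d1_0 + (config$d1_max - config$d1_0) * frac
  d2 <- config$d2_0 + (config$d2_max - config$d2_0) * frac
  g <- (d2 - d) / (d2 - d1)
  pmin(1, pmax(0, g))
}

#' Breakpoints of the search gain at a given searching time
#'
#' @param t searching time in steps.
#' @param config an [acs_config()].
#' @return named numeric `c(d1, d2)` in length units.
#' @export
acs_breakpoints <- function(t, config = acs_config()) {
  frac <- pmin(t / config$t_max, 1)
  c(d1 = config$d1_0 + (config$d1_max - config$d1_0) * frac,
    d2 = config$d2_0 + (config$d2_max - config$d2_0) * frac)
}

#' Output vector of the random search generator
#'
#' The generator proposes the previous heading changed by a random turn,
#' with unit length multiplied by the activation of the `ACSon` motivation
#' unit: the motivation network, driven by the gain [acs_gain()] and
#' inhibited by landmark perception, decides how much the random proposal
#' may contribute.
#'
#' @param prev_heading the agent's heading on the previous step (radians).
#' @param turn a heading change, e.g. from [draw_turn()].
#' @param acs_on_activation activation of the `ACSon` unit in `[0, 1]`.
#' @return a [polar_vector()] with angle `prev_heading + turn` and length
#'   `acs_on_activation`.
#' @export
acs_output <- function(prev_heading, turn, acs_on_activation) {
  stopifnot(acs_on_activation >= 0)
  polar_vector(prev_heading + turn, min(1, acs_on_activation))
}
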