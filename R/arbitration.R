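#' Arbitration configuration
#'
#' Parameters of the competition stage that turns raw procedure saliences
#' into summation weights.
#'
#' @param b inhibitory weight of the feedforward lateral-inhibition
#'   network (negative; default -0.4).
#' @param pi_acs_scale factor applied to the path-integrator and
#'   random-generator saliences before inhibition (default 0.2), which
#'   guarantees that any active landmark overrides both.
#' @param eps threshold above which a summed landmark salience counts as
#'   "a landmark is active" and zeroes the path-integrator salience.
#' @param eps_dir resultants shorter than this keep the previous heading.
#' @return a list of class `arbitration_config`.
#' @export
arbitration_config <- function(b = -0.4, pi_acs_scale = 0.2,
                               eps = 1e-9, eps_dir = 1e-9) {
  stopifnot(b < 0, pi_acs_scale > 0)
  structure(list(b = b, pi_acs_scale = pi_acs_scale,
                 eps = eps, eps_dir = eps_dir),
            class = "arbitration_config")
}

#' One-layered feedforward lateral inhibition
#'
#' Each competitor's output is its salience minus `|b|` times the summed
#' saliences of the competitors allowed to inhibit it, rectified at zero.
#' With `b = -0.4` a competitor wins outright (all rivals zeroed) whenever
#' its salience is at least 2.5 times the runner-up's; close competitors
#' are both reduced and contribute mixedly. Inhibition is asymmetric
#' within the landmark pool: place (food/home) elements inhibit route
#' elements but not vice versa, so landmarks that signal the goal itself
#' outweigh en-route landmarks. The path-integrator/random-generator pool
#' is symmetric.
#'
#' @param salience named non-negative salience vector.
#' @param kind character vector, same length: `"route"`, `"place"`,
#'   `"pi"`, or `"acs"`; determines the allowed inhibitory edges.
#' @param b inhibitory weight (negative).
#' @return named vector of post-inhibition weights (all `>= 0`).
#' @export
#' @examples
#' lateral_inhibit(c(new = 1, old = 0.4), c("route", "route"))
lateral_inhibit <- function(salience, kind, b = -0.4) {
  stopifnot(is.numeric(salience), all(salience >= 0), b < 0,
            length(kind) == length(salience),
            all(kind %in% c("route", "place", "pi", "acs")))
  n <- length(salience)
  out <- numeric(n)
  for (i in seq_len(n)) {
    allowed <- switch(kind[i],
      route = kind %in% c("route", "place"),
      place = kind == "place",
      pi    = kind == "acs",
      acs   = kind == "pi")
    allowed[i] <- FALSE
    out[i] <- max(0, salience[i] + b * sum(salience[allowed]))
  }
  names(out) <- names(salience)
  out
}

#' Landmark suppression of the path integrator
#'
#' Whenever any landmark memory is active (summed landmark salience above
#' `eps`), the path-integrator salience is zeroed: a recognized landmark
#' is followed instead of the home/goal vector. The same landmark sum also
#' drives the `ACSoff` motivation unit (see [event_drives()]), switching
#' the search generator off.
#'
#' @param landmark_salience_sum summed salience of all landmark elements.
#' @param pi_salience the path integrator's salience.
#' @param eps activity threshold.
#' @return the (possibly zeroed) path-integrator salience.
#' @export
suppress_pi <- function(landmark_salience_sum, pi_salience, eps = 1e-9) {
  if (landmark_salience_sum > eps) 0 else pi_salience
}

#' Resolve all procedure outputs into a single heading
#'
#' The full arbitration pipeline: scale the path-integrator and
#' random-generator saliences by `pi_acs_scale`, zero the path integrator
#' if any landmark is active, run lateral inhibition separately within the
#' landmark pool and within the PI/search pool, then sum all proposals as
#' weight-scaled unit vectors ([weighted_vector_sum()]). The angle of the
#' resultant is the commanded heading; if the resultant is shorter than
#' `eps_dir` the previous heading is kept.
#'
#' Within the PI/search pool the search motivation gates the integrator
#' reciprocally: the PI salience is additionally scaled by `1 - ACSon`
#' (the length of `acs_vec`). When the integrator reports a near-zero
#' goal distance the search unit saturates and random turns govern the
#' output alone; as the random walk carries the agent away, the gain and
#' with it `ACSon` fall, the two procedures blend, and far enough out
#' path integration controls the output completely — the mechanism from
#' which area-concentrated search emerges without being programmed.
#'
#' @param landmarks data.frame with columns `id`, `kind`, `angle`,
#'   `salience` (as produced by [landmark_outputs()]).
#' @param pi_vec the path-integrator output, a [polar_vector()] of length
#'   1 or 0 ([pi_output()]).
#' @param acs_vec the search-generator output, a [polar_vector()] whose
#'   length is the `ACSon` activation ([acs_output()]).
#' @param prev_heading previous heading (radians), the fallback.
#' @param config an [arbitration_config()].
#' @return a list: `heading` (radians), `weights` (named post-inhibition
#'   weights of every procedure, landmark ids plus `"PI"` and `"ACS"`),
#'   `pre` (pre-inhibition saliences entering the pools), `winner` (id of
#'   the largest weight, or `"none"`), `lm_sum`, `total_length`.
#' @export
resolve_heading <- function(landmarks, pi_vec, acs_vec, prev_heading,
                            config = arbitration_config()) {
  stopifnot(inherits(pi_vec, "polar_vector"),
            inherits(acs_vec, "polar_vector"))
  lm_sum <- if (nrow(landmarks)) sum(landmarks$salience) else 0
  acs_on <- min(1, acs_vec$length)
  s_pi <- suppress_pi(lm_sum,
                      config$pi_acs_scale * pi_vec$length * (1 - acs_on),
                      config$eps)
  s_acs <- config$pi_acs_scale * acs_vec$length
  w_lm <- if (nrow(landmarks)) {
    lateral_inhibit(stats::setNames(landmarks$salience, landmarks$id),
                    landmarks$kind, config$b)
  } else stats::setNames(numeric(0), character(0))
  w_pa <- lateral_inhibit(c(PI = s_pi, ACS = s_acs),
                          c("pi", "acs"), config$b)
  angles <- c(landmarks$angle, pi_vec$angle, acs_vec$angle)
  weights <- c(w_lm, w_pa)
  res <- weighted_vector_sum(angles, weights)
  heading <- if (res$length < config$eps_dir) prev_heading else res$angle
  winner <- if (any(weights > 0)) names(weights)[which.max(weights)]
            else "none"
  list(heading = heading, weights = weights,
       pre = c(stats::setNames(landmarks$salience, landmarks$id),
               PI = s_pi, ACS = s_acs),
       winner = winner, lm_sum = lm_sum, total_length = res$length)
}
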