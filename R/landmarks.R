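#' Route-landmark memory element
#'
#' A route landmark associates a circular catchment area with a fixed
#' compass direction ("local vector"). When the agent enters the catchment
#' while both gating motivations (trip direction and goal source) are above
#' threshold, the element is triggered: it emits its local angle with
#' salience 1, sampled once and then held while the salience decays over 15
#' steps (see [route_salience()]). Elements are fully independent: no
#' ordering among landmarks is stored anywhere.
#'
#' @param id unique element id.
#' @param center catchment center, `c(x, y)`.
#' @param radius catchment radius in length units (default 20, two steps).
#' @param local_angle compass direction followed after the trigger
#'   (radians).
#' @param gate_source food-source id this element belongs to ("A", "B",
#'   ...).
#' @param gate_direction `"outbound"` or `"inbound"`.
#' @return a list of class `route_landmark`.
#' @export
route_landmark <- function(id, center, radius = 20, local_angle,
                           gate_source, gate_direction) {
  stopifnot(is.character(id), length(center) == 2L, radius > 0,
            gate_direction %in% c("outbound", "inbound"))
  structure(list(id = id, kind = "route", center = as.numeric(center),
                 radius = radius, local_angle = wrap_angle(local_angle),
                 gate_source = gate_source,
                 gate_direction = gate_direction),
            class = "route_landmark")
}

#' Place-landmark memory element (snapshot)
#'
#' A place landmark stores a "snapshot" of its goal location: the vectors
#' from the goal to three surrounding signposts, learned while standing at
#' the goal. While the agent is inside the catchment and the gates pass,
#' the element continuously compares the currently seen signpost vectors
#' with the stored ones and emits a homing direction with salience 1
#' ([snapshot_output()]); walking along that direction improves the match
#' until the goal is reached. The home landmark is gated by `inbound` only;
#' food landmarks by `outbound` plus their source.
#'
#' @param id unique element id.
#' @param goal the place the element guides to, `c(x, y)`.
#' @param radius catchment radius (default 25).
#' @param signposts 3 x 2 matrix of signpost positions; defaults to three
#'   points placed 60 units from the goal at 120 degree spacing.
#' @param learned 3 x 2 matrix of learned goal-to-signpost vectors;
#'   defaults to the true vectors (learning is not simulated, memories are
#'   installed "by hand").
#' @param gate_source food-source id or `NULL` for the home landmark.
#' @param gate_direction `"outbound"` or `"inbound"`.
#' @return a list of class `place_landmark`.
#' @export
place_landmark <- function(id, goal, radius = 25, signposts = NULL,
                           learned = NULL, gate_source = NULL,
                           gate_direction) {
  stopifnot(is.character(id), length(goal) == 2L, radius > 0,
            gate_direction %in% c("outbound", "inbound"))
  goal <- as.numeric(goal)
  if (is.null(signposts)) {
    ang <- c(0, 2 * pi / 3, 4 * pi / 3) + pi / 6
    signposts <- cbind(goal[1] + 60 * cos(ang), goal[2] + 60 * sin(ang))
  }
  signposts <- matrix(as.numeric(signposts), ncol = 2)
  stopifnot(nrow(signposts) == 3L)
  if (is.null(learned))
    learned <- sweep(signposts, 2, goal)
  learned <- matrix(as.numeric(learned), ncol = 2)
  stopifnot(nrow(learned) == 3L)
  structure(list(id = id, kind = "place", goal = goal, radius = radius,
                 signposts = signposts, learned = learned,
                 gate_source = gate_source,
                 gate_direction = gate_direction),
            class = "place_landmark")
}

.gates_pass <- function(element, motivation, threshold = 0.5) {
  if (motivation[[element$gate_direction]] < threshold) return(FALSE)
  if (!is.null(element$gate_source)) {
    unit <- paste0("source", element$gate_source)
    if (motivation[[unit]] < threshold) return(FALSE)
  }
  TRUE
}

#' Route-landmark trigger and decay bookkeeping
#'
#' Advances one element's decay counter for one simulation step. If the
#' agent is inside the catchment and both gates pass, the counter is set to
#' 0 (re-entry retriggers, so a newly recognized landmark overrides an
#' older one); otherwise an active counter increments. If the gates fail,
#' the element is deactivated: a memory may only act within the
#' motivational context in which it applies.
#'
#' @param element a [route_landmark()].
#' @param agent_pos agent position `c(x, y)`.
#' @param motivation named activation vector.
#' @param steps_since_trigger current counter (integer, `NA` = inactive).
#' @param threshold gate threshold.
#' @return the updated counter (`NA` when inactive).
#' @export
route_trigger <- function(element, agent_pos, motivation,
                          steps_since_trigger = NA_integer_,
                          threshold = 0.5) {
  stopifnot(inherits(element, "route_landmark"))
  if (!.gates_pass(element, motivation, threshold)) return(NA_integer_)
  inside <- dist_xy(agent_pos, element$center) <= element$radius
  if (inside) return(0L)
  if (is.na(steps_since_trigger)) return(NA_integer_)
  k <- steps_since_trigger + 1L
  if (route_salience(k) <= 0) return(NA_integer_)
  k
}

#' Route-landmark salience decay schedule
#'
#' Salience is 1 at the moment the landmark is perceived, then "forgets"
#' stepwise: it decreases by 0.05 per step for ten steps (reaching 0.5),
#' stays at 0.5 for another five steps, and drops to zero after step 15.
#' The decay lets a newly recognized landmark override the memory of an
#' earlier one, and bounds how far a local vector is run off.
#'
#' @param k integer steps since the trigger (`k = 0` at perception).
#' @return salience in `[0, 1]`; vectorized over `k`.
#' @export
#' @examples
#' route_salience(c(0, 5, 10, 12, 15, 16))
route_salience <- function(k) {
  stopifnot(is.numeric(k), all(is.finite(k)))
  if (any(k < 0)) stop("steps since trigger must be non-negative")
  k <- as.integer(k)
  out <- numeric(length(k))
  out[k <= 10] <- 1 - 0.05 * k[k <= 10]
  out[k > 10 & k <= 15] <- 0.5
  out[k > 15] <- 0
  out
}

#' Snapshot matching output of a place landmark
#'
#' For each of the three signposts the element forms a correction vector:
#' the currently seen agent-to-signpost vector minus the stored
#' goal-to-signpost vector. The mean of the three corrections points from
#' the agent towards the stored goal; its angle is emitted with length
#' normalized to 1. When the mean correction is shorter than `eps` the
#' agent has reached the goal and the output length is 0.
#'
#' @param element a [place_landmark()].
#' @param agent_pos agent position `c(x, y)`.
#' @param eps goal-match radius in length units.
#' @return a [polar_vector()] with length 1 (homing direction) or 0 (at
#'   goal).
#' @export
snapshot_output <- function(element, agent_pos, eps = 1.0) {
  stopifnot(inherits(element, "place_landmark"))
  seen <- sweep(element$signposts, 2, as.numeric(agent_pos))
  corr <- seen - element$learned
  m <- colMeans(corr)
  len <- sqrt(sum(m^2))
  if (len < eps) return(polar_vector(0, 0))
  polar_vector(atan2(m[2], m[1]), 1)
}

#' Evaluate the whole landmark bank for one step
#'
#' Applies [route_trigger()] bookkeeping to every route element and
#' snapshot matching to every place element, respecting the motivational
#' gates, and collects the per-element outputs (angle, salience, kind) for
#' the arbitration stage.
#'
#' @param bank list of [route_landmark()] / [place_landmark()] elements.
#' @param counters named integer vector of route decay counters (names =
#'   element ids; `NA` = inactive).
#' @param agent_pos agent position `c(x, y)`.
#' @param motivation named activation vector.
#' @param threshold gate threshold.
#' @return a list: `outputs` (data.frame `id`, `kind`, `angle`, `salience`)
#'   and `counters` (updated).
#' @export
landmark_outputs <- function(bank, counters, agent_pos, motivation,
                             threshold = 0.5) {
  ids <- vapply(bank, `[[`, "", "id")
  kinds <- vapply(bank, `[[`, "", "kind")
  angle <- numeric(length(bank))
  salience <- numeric(length(bank))
  for (i in seq_along(bank)) {
    el <- bank[[i]]
    if (el$kind == "route") {
      k <- route_trigger(el, agent_pos, motivation,
                         counters[[el$id]], threshold)
      counters[[el$id]] <- k
      if (!is.na(k)) {
        angle[i] <- el$local_angle
        salience[i] <- route_salience(k)
      }
    } else {
      inside <- dist_xy(agent_pos, el$goal) <= el$radius
      if (inside && .gates_pass(el, motivation, threshold)) {
        out <- snapshot_output(el, agent_pos)
        angle[i] <- out$angle
        salience[i] <- out$length
      }
    }
  }
  list(outputs = data.frame(id = ids, kind = kinds, angle = angle,
                            salience = salience,
                            stringsAsFactors = FALSE),
       counters = counters)
}
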