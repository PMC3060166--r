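#' Canonical two-food-source world
#'
#' The standard test environment: a nest at the origin, food source A in
#' the upper right, food source B in the lower right, and twelve route
#' landmarks — three per trip (A-outbound, A-inbound, B-outbound,
#' B-inbound), each trip's elements gated by its own source and direction
#' motivations. The A-outbound chain starts on the direct nest-to-A line
#' and detours via local vectors that hand over from landmark to landmark
#' until the last one points at the food source. The B-inbound chain's
#' first element sits on the direct B-to-nest line, and its local vector
#' points at a landmark too far away to be reached before the local vector
#' has run off, so path integration must take over. Place (snapshot)
#' landmarks sit at the nest and both food sources. Exact coordinates are
#' package fixtures, not measured data.
#'
#' @param has_food_A,has_food_B availability flags of the two sources.
#' @return a list with `nest`, `food`, and `landmarks`, for [scenario()].
#' @export
two_food_world <- function(has_food_A = TRUE, has_food_B = TRUE) {
  nest <- c(0, 0)
  A <- c(350, 250)
  B <- c(350, -250)
  rl <- function(id, center, to, src, dir)
    route_landmark(id, center,
                   local_angle = angle_between(center, to),
                   gate_source = src, gate_direction = dir)
  ## A-outbound chain: first element on the nest->A line, chained to A
  a1 <- c(122.1, 87.2); a2 <- c(235, 75); a3 <- c(340, 110)
  ## A-inbound elements north of the A->nest line (not met on the
  ## canonical inbound leg)
  ai1 <- c(250, 220); ai2 <- c(150, 170); ai3 <- c(60, 90)
  ## B-outbound elements south of the nest->B line (not met)
  bo1 <- c(150, -260); bo2 <- c(250, -300); bo3 <- c(320, -290)
  ## B-inbound: first element on the B->nest line, pointing at a second
  ## element out of local-vector reach; third is off every canonical path
  bi1 <- c(210, -150); bi2 <- c(-20, -200); bi3 <- c(120, -60)
  landmarks <- list(
    rl("rA_out1", a1, a2, "A", "outbound"),
    rl("rA_out2", a2, a3, "A", "outbound"),
    rl("rA_out3", a3, A, "A", "outbound"),
    rl("rA_in1", ai1, ai2, "A", "inbound"),
    rl("rA_in2", ai2, ai3, "A", "inbound"),
    rl("rA_in3", ai3, nest, "A", "inbound"),
    rl("rB_out1", bo1, bo2, "B", "outbound"),
    rl("rB_out2", bo2, bo3, "B", "outbound"),
    rl("rB_out3", bo3, B, "B", "outbound"),
    rl("rB_in1", bi1, bi2, "B", "inbound"),
    rl("rB_in2", bi2, nest, "B", "inbound"),
    rl("rB_in3", bi3, nest, "B", "inbound"),
    place_landmark("fLMA", A, gate_source = "A",
                   gate_direction = "outbound"),
    place_landmark("fLMB", B, gate_source = "B",
                   gate_direction = "outbound"),
    place_landmark("hLM", nest, gate_direction = "inbound"))
  list(nest = nest,
       food = list(A = list(pos = A, has_food = has_food_A),
                   B = list(pos = B, has_food = has_food_B)),
       landmarks = landmarks)
}

#' Scenario: landmark-guided trip to a food source and back
#'
#' A trip from the nest to one source of the [two_food_world()] and back.
#' With `target = "A"` the outbound leg is handed from route landmark to
#' route landmark while the inbound leg is pure path integration (crossing
#' one outbound catchment, which is ignored because the outbound
#' motivation is off). With `target = "B"` the outbound leg is pure path
#' integration and the inbound leg picks up a route landmark whose local
#' vector runs off before the next landmark is reached, after which path
#' integration resumes.
#'
#' @param target `"A"` or `"B"`.
#' @param seed RNG seed.
#' @return an [scenario()].
#' @export
scenario_route_trip <- function(target = "A", seed = 1L) {
  w <- two_food_world()
  scenario(nest = w$nest, food = w$food, landmarks = w$landmarks,
           target = target, max_steps = 400L, seed = seed,
           name = paste0("route_trip_", target))
}

#' Scenario: shortcut between two food sources
#'
#' The agent heads for source A, finds it emptied, and — because the
#' motivation network immediately hands the goal to source B — walks a
#' novel direct path from A to B steered by path integration alone: the
#' reference vector of B minus the current vector (which at that moment
#' numerically equals vector A) points along B - A, although no memory
#' arithmetic between the two stored vectors ever happens. After finding
#' food at B it returns home.
#'
#' @param seed RNG seed.
#' @return an [scenario()].
#' @export
scenario_shortcut <- function(seed = 1L) {
  w <- two_food_world(has_food_A = FALSE, has_food_B = TRUE)
  scenario(nest = w$nest, food = w$food, landmarks = w$landmarks,
           target = "A", max_steps = 500L, seed = seed,
           name = "shortcut")
}

#' Scenario: displaced forager (capture at the feeder, release elsewhere)
#'
#' A forager flies from the hive to a feeder 400 units east, is captured
#' the moment it finds food, and is passively transported 300 units north
#' of the feeder. Passive transport leaves the current vector untouched,
#' so on release the agent flies the full home vector westwards, ends up
#' north of the hive, and — being now effectively a zero-vector agent —
#' starts an area-concentrated search. As soon as the search crosses the
#' catchment of a known inbound route landmark, local vectors chain it
#' back to the hive.
#'
#' @param seed RNG seed.
#' @return an [scenario()].
#' @export
scenario_displaced_forager <- function(seed = 1L) {
  nest <- c(0, 0)
  A <- c(400, 0)
  rl <- function(id, center, to)
    route_landmark(id, center, local_angle = angle_between(center, to),
                   gate_source = "A", gate_direction = "inbound")
  l1 <- c(0, 220); l2 <- c(0, 140); l3 <- c(0, 60)
  landmarks <- list(
    rl("rin1", l1, l2), rl("rin2", l2, l3), rl("rin3", l3, nest),
    rl("rin4", c(100, 250), l1), rl("rin5", c(-100, 250), l1),
    rl("rin6", c(100, 150), l2), rl("rin7", c(-100, 150), l2),
    place_landmark("fLMA", A, gate_source = "A",
                   gate_direction = "outbound"),
    place_landmark("hLM", nest, gate_direction = "inbound"))
  scenario(nest = nest,
           food = list(A = list(pos = A, has_food = TRUE)),
           landmarks = landmarks, target = "A",
           interventions = list(list(on_event = "food_found",
                                     action = "displace",
                                     pos = c(400, 300),
                                     reset_current = FALSE)),
           max_steps = 3000L, seed = seed,
           name = "displaced_forager")
}

#' Scenario: zero-vector release inside a food catchment
#'
#' The agent is caught when leaving the nest (current vector still zero)
#' and released inside the catchment area of food source A, which has
#' been emptied. The place landmark of A guides it to the empty site; the
#' motivation network then hands the goal to source B — and because only
#' the reference vector of B can steer (the current vector is still close
#' to zero), the agent heads along vector B as seen from the nest, not
#' along B - A. A system that could subtract stored vectors would head
#' along B - A instead; the difference is the experimentally testable
#' signature of the decentralized memory.
#'
#' @param seed RNG seed.
#' @return an [scenario()].
#' @export
scenario_zero_vector_release <- function(seed = 1L) {
  w <- two_food_world(has_food_A = FALSE, has_food_B = TRUE)
  scenario(nest = w$nest, food = w$food, landmarks = w$landmarks,
           target = "A",
           agent = list(start = c(327, 250), current = c(0, 0)),
           max_steps = 150L, seed = seed,
           name = "zero_vector_release")
}

#' Scenario: emergent area-concentrated search
#'
#' A zero-vector agent in a featureless world: its current vector says
#' "home is here", but there is nothing here (the true nest is far out of
#' reach, as after a long-distance displacement). No search routine is
#' programmed; the looping, origin-centred search emerges from blending
#' the biased random-turn generator (strong while the path integrator
#' reports a near-zero goal distance) with the path integrator (which
#' pulls back as soon as the random walk has carried the agent away).
#'
#' @param seed RNG seed.
#' @param max_steps run length.
#' @return an [scenario()]; the release point/search origin is `c(0, 0)`.
#' @export
scenario_search <- function(seed = 1L, max_steps = 1000L) {
  scenario(nest = c(100000, 0),
           food = list(A = list(pos = c(100400, 0), has_food = TRUE)),
           landmarks = list(),
           agent = list(start = c(0, 0), current = c(0, 0),
                        motivation = c(forage = 1, sourceA = 1,
                                       inbound = 1)),
           max_steps = max_steps, seed = seed,
           stop_at_home = TRUE, name = "search")
}

#' Generate a randomized scenario
#'
#' Emits a random world in the style of the canonical ones: a nest at the
#' origin, one or two food sources a few hundred units away, optional
#' route-landmark chains along each leg (spaced so that each local vector
#' can hand over to the next element), and place landmarks at the nest
#' and every food source. Useful as a property-test fixture and for
#' exploring the architecture beyond the hand-authored worlds.
#'
#' @param seed RNG seed for world generation (also stored as the
#'   scenario's run seed).
#' @param n_sources 1 or 2 food sources.
#' @param n_route_per_leg route landmarks per (source, direction) leg,
#'   0 to 3; default drawn at random.
#' @return an [scenario()].
#' @export
random_scenario <- function(seed = 1L, n_sources = 2L,
                            n_route_per_leg = NULL) {
  stopifnot(n_sources %in% 1:2)
  rng <- rng_stream(seed)
  runi <- function(a, b) rng_uniform(rng, 1L, a, b)
  nest <- c(0, 0)
  ids <- c("A", "B")[seq_len(n_sources)]
  food <- list()
  landmarks <- list()
  base_angle <- runi(-pi, pi)
  for (i in seq_along(ids)) {
    id <- ids[i]
    ang <- wrap_angle(base_angle + (i - 1) * runi(1.5, 2.5))
    dist <- runi(280, 420)
    goal <- dist * c(cos(ang), sin(ang))
    food[[id]] <- list(pos = goal, has_food = TRUE)
    for (dir in c("outbound", "inbound")) {
      n_lm <- if (is.null(n_route_per_leg))
        floor(runi(0, 3.999)) else n_route_per_leg
      if (n_lm == 0) next
      from <- if (dir == "outbound") nest else goal
      to <- if (dir == "outbound") goal else nest
      leg <- to - from
      leg_len <- sqrt(sum(leg^2))
      u <- leg / leg_len
      ## first element sits on the leg so a straight walk triggers it;
      ## later elements are spaced within local-vector reach of each other
      centers <- list(from + runi(0.25, 0.4) * leg_len * u)
      for (k in seq_len(n_lm - 1L)) {
        prev <- centers[[k]]
        step_d <- runi(100, 130)
        jitter <- runi(-0.25, 0.25)
        dir_vec <- to - prev
        dir_ang <- atan2(dir_vec[2], dir_vec[1]) + jitter
        centers[[k + 1L]] <- prev + step_d * c(cos(dir_ang), sin(dir_ang))
      }
      for (k in seq_len(n_lm)) {
        nxt <- if (k < n_lm) centers[[k + 1L]] else to
        landmarks[[length(landmarks) + 1L]] <-
          route_landmark(sprintf("r%s_%s%d", id, substr(dir, 1, 3), k),
                         centers[[k]],
                         local_angle = angle_between(centers[[k]], nxt),
                         gate_source = id, gate_direction = dir)
      }
    }
    landmarks[[length(landmarks) + 1L]] <-
      place_landmark(paste0("fLM", id), goal, gate_source = id,
                     gate_direction = "outbound")
  }
  landmarks[[length(landmarks) + 1L]] <-
    place_landmark("hLM", nest, gate_direction = "inbound")
  scenario(nest = nest, food = food, landmarks = landmarks,
           target = ids[1], max_steps = 600L, seed = seed,
           name = sprintf("random_%d", as.integer(seed)))
}
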