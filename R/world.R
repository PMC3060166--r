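#' Build a simulation scenario
#'
#' A scenario bundles the static configuration of one simulated world: nest
#' and food positions, the landmark bank, pre-installed reference-vector
#' memories (learning itself is not simulated; memories are switched on by
#' hand), network parameters, the agent's initial state, and experimenter
#' interventions (capture-and-release displacement, food removal).
#'
#' @param nest nest position `c(x, y)`.
#' @param food named list of food sources, each `list(pos = c(x, y),
#'   has_food = TRUE/FALSE)`; names must be `"A"` and/or `"B"` (they map
#'   onto the `sourceA`/`sourceB` motivation units).
#' @param landmarks list of [route_landmark()] / [place_landmark()]
#'   elements; ids must be unique.
#' @param memories a [reference_memories()] bank; default: the true
#'   nest-to-food vector of every source (a fully trained forager).
#' @param target which source the agent initially intends to visit.
#' @param weights a [default_motivation_weights()] object.
#' @param arbitration an [arbitration_config()].
#' @param acs an [acs_config()].
#' @param agent list with `start` (position; default the nest), `heading`
#'   (radians), `motivation` (named initial activations; default a forager
#'   heading outbound to `target`), `current` (initial current vector as
#'   `c(x, y)`, default zero).
#' @param interventions list of interventions, each a list with either
#'   `at_step` (integer) or `on_event` (event code prefix, e.g.
#'   `"food_found"`), and `action = "displace"` (`pos`, `reset_current`)
#'   or `action = "set_food"` (`source`, `has_food`).
#' @param eps_goal detection radius for nest and food (length units).
#' @param step_length forward displacement per step (fixed; velocity is
#'   not under network control).
#' @param eps_pi zero-state radius of the path integrator.
#' @param gate_threshold motivation level above which a gate passes.
#' @param max_steps simulation cap.
#' @param seed default RNG seed for [run_scenario()].
#' @param stop_at_home end the run when the agent enters the nest inbound.
#' @param name scenario label used in logs and plots.
#' @return a list of class `antnav_scenario`.
#' @export
scenario <- function(nest = c(0, 0),
                     food = list(A = list(pos = c(350, 250),
                                          has_food = TRUE)),
                     landmarks = list(),
                     memories = NULL,
                     target = names(food)[1],
                     weights = default_motivation_weights(),
                     arbitration = arbitration_config(),
                     acs = acs_config(),
                     agent = list(),
                     interventions = list(),
                     eps_goal = 10,
                     step_length = 10,
                     eps_pi = 1.0,
                     gate_threshold = 0.5,
                     max_steps = 500L,
                     seed = 1L,
                     stop_at_home = TRUE,
                     name = "scenario") {
  if (is.null(memories)) {
    memories <- reference_memories(names(food))
    for (id in names(food)) {
      d <- food[[id]]$pos - nest
      memories[[id]] <- pv_from_xy(d[1], d[2])
    }
  }
  if (is.null(agent$start)) agent$start <- nest
  if (is.null(agent$heading)) agent$heading <- 0
  if (is.null(agent$current)) agent$current <- c(0, 0)
  if (is.null(agent$motivation)) {
    agent$motivation <- stats::setNames(
      c(1, 1, 1), c("forage", paste0("source", target), "outbound"))
  }
  sc <- structure(
    list(nest = as.numeric(nest), food = food, landmarks = landmarks,
         memories = memories, target = target, weights = weights,
         arbitration = arbitration, acs = acs, agent = agent,
         interventions = interventions, eps_goal = eps_goal,
         step_length = step_length, eps_pi = eps_pi,
         gate_threshold = gate_threshold, max_steps = as.integer(max_steps),
         seed = as.integer(seed), stop_at_home = stop_at_home, name = name),
    class = "antnav_scenario")
  validate_scenario(sc)
  sc
}

#' Validate a scenario
#'
#' Checks id uniqueness, that every landmark and memory refers to an
#' existing food source, and that numeric parameters are admissible.
#'
#' @param sc an [scenario()] object.
#' @return invisibly `TRUE`; otherwise an error.
#' @export
validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "antnav_scenario"))
  src_ids <- names(sc$food)
  if (is.null(src_ids) || anyDuplicated(src_ids))
    stop("food sources must have unique names")
  if (!all(src_ids %in% c("A", "B")))
    stop("food source ids must be 'A' and/or 'B'")
  for (f in sc$food)
    if (length(f$pos) != 2L || !is.logical(f$has_food))
      stop("each food source needs pos = c(x, y) and has_food flag")
  if (!sc$target %in% src_ids)
    stop(sprintf("target '%s' is not a food source", sc$target))
  ids <- vapply(sc$landmarks, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("landmark ids must be unique")
  for (el in sc$landmarks) {
    if (!el$kind %in% c("route", "place")) stop("unknown landmark kind")
    if (el$radius <= 0) stop("catchment radius must be positive")
    if (!is.null(el$gate_source) && !el$gate_source %in% src_ids)
      stop(sprintf("landmark '%s' gates on unknown source '%s'",
                   el$id, el$gate_source))
  }
  if (!all(names(sc$memories) %in% src_ids))
    stop("reference memory for unknown source")
  for (iv in sc$interventions) {
    if (!iv$action %in% c("displace", "set_food"))
      stop(sprintf("unknown intervention action '%s'", iv$action))
    if (is.null(iv$at_step) && is.null(iv$on_event))
      stop("intervention needs at_step or on_event")
    if (iv$action == "set_food" && !iv$source %in% src_ids)
      stop("set_food intervention on unknown source")
  }
  stopifnot(sc$eps_goal > 0, sc$step_length > 0, sc$max_steps >= 1)
  invisible(TRUE)
}

#' Initialize the mutable world state of a run
#'
#' The returned world is a plain R value (no environments): assigning it
#' to another variable is a full checkpoint, and resuming from a stored
#' copy reproduces the remainder of the run bit-for-bit.
#'
#' @param sc an [scenario()].
#' @param seed RNG seed; defaults to the scenario's.
#' @return a list of class `antnav_world`.
#' @export
world_init <- function(sc, seed = NULL) {
  stopifnot(inherits(sc, "antnav_scenario"))
  if (is.null(seed)) seed <- sc$seed
  route_ids <- vapply(Filter(function(e) e$kind == "route", sc$landmarks),
                      `[[`, "", "id")
  counters <- stats::setNames(rep(NA_integer_, length(route_ids)),
                              route_ids)
  mot <- motivation_state(sc$agent$motivation)
  at_nest <- dist_xy(sc$agent$start, sc$nest) <= sc$eps_goal
  structure(list(
    pos = as.numeric(sc$agent$start),
    heading = sc$agent$heading,
    current = as.numeric(sc$agent$current),
    mot = mot,
    counters = counters,
    memories = sc$memories,
    food_has = stats::setNames(
      vapply(sc$food, function(f) isTRUE(f$has_food), TRUE), names(sc$food)),
    acs_timer = 0L,
    lm_sum_prev = 0,
    has_left = !at_nest,
    carrying = FALSE,
    denied = stats::setNames(logical(length(sc$food)), names(sc$food)),
    iv_applied = logical(length(sc$interventions)),
    rng = rng_snapshot(rng_stream(seed)),
    step = 0L,
    done = FALSE,
    last_record = NULL),
    class = "antnav_world")
}

.active_source <- function(mot_a, src_ids, threshold) {
  for (id in src_ids)
    if (mot_a[[paste0("source", id)]] >= threshold) return(id)
  NA_character_
}

.leg_label <- function(mot_a, threshold) {
  if (mot_a[["outbound"]] >= threshold) "outbound"
  else if (mot_a[["inbound"]] >= threshold) "inbound"
  else "none"
}

#' Advance the world by one simulation step
#'
#' The ordered pipeline of one behavioural step: (1) sense events (nest
#' departure/entry, food found or missing at the motivationally targeted
#' source); (2) map events plus the continuous search-gain and
#' landmark-sum signals to drives and relax the motivation network; (3)
#' evaluate all gated memory outputs (path integrator, route and place
#' landmarks, random search generator); (4) arbitrate them into a heading;
#' (5) apply any triggered intervention, otherwise move `step_length`
#' units along the heading; (6) update the current vector with the actual
#' displacement (passive displacement leaves it untouched); (7) record.
#'
#' @param world an [world_init()] state.
#' @param sc the matching [scenario()].
#' @return the updated world; `world$last_record` holds the step's log row
#'   and `world$done` flags termination.
#' @export
sim_step <- function(world, sc) {
  stopifnot(inherits(world, "antnav_world"), inherits(sc, "antnav_scenario"))
  if (world$done) return(world)
  th <- sc$gate_threshold
  step <- world$step + 1L
  rng <- rng_restore(world$rng)
  events <- character(0)
  mot_a <- world$mot$a

  ## (1) sense position-based events
  d_nest <- dist_xy(world$pos, sc$nest)
  at_nest <- d_nest <= sc$eps_goal
  if (!world$has_left && !at_nest) {
    events <- c(events, "left_nest")
    world$has_left <- TRUE
  }
  entered <- FALSE
  if (mot_a[["outbound"]] >= th) {
    src <- .active_source(mot_a, names(sc$food), th)
    if (!is.na(src)) {
      near <- dist_xy(world$pos, sc$food[[src]]$pos) <= sc$eps_goal
      if (near && world$food_has[[src]] && !world$carrying) {
        events <- c(events, "food_found")
        world$carrying <- TRUE
        world$memories <- store_reference(
          world$memories, src, pv_from_xy(world$current[1],
                                          world$current[2]))
      } else if (near && !world$food_has[[src]] && !world$denied[[src]]) {
        events <- c(events, paste0("food_absent:", src))
        world$denied[[src]] <- TRUE
      } else if (!near) {
        world$denied[[src]] <- FALSE
      }
    }
  }
  if (mot_a[["inbound"]] >= th && at_nest && world$has_left) {
    events <- c(events, "entered_nest")
    world$current <- c(0, 0)       # reset only on nest entry
    world$carrying <- FALSE
    world$acs_timer <- 0L
    entered <- TRUE
  }

  ## (2) drives and motivation relaxation
  cur_pv <- pv_from_xy(world$current[1], world$current[2])
  ref_pre <- gated_reference(world$memories, mot_a, th)
  d_goal_pre <- pv_sub(ref_pre, cur_pv)$length
  gain <- acs_gain(d_goal_pre, world$acs_timer, sc$acs)
  drives <- event_drives(events, landmark_sum = world$lm_sum_prev,
                         acs_gain = gain,
                         acs_off_gain = sc$weights$acs_off_gain)
  if (length(events))   # seeded tie-break noise at event time
    drives <- drives + rng_uniform(rng, length(drives), -1e-6, 1e-6)
  rel <- relax_motivation(world$mot, sc$weights, drives)
  world$mot <- rel$state
  mot_a <- world$mot$a

  ## (3) gated memory outputs
  lo <- landmark_outputs(sc$landmarks, world$counters, world$pos, mot_a, th)
  world$counters <- lo$counters
  lm_sum <- sum(lo$outputs$salience)
  ref <- gated_reference(world$memories, mot_a, th)
  piv <- pi_output(ref, cur_pv, sc$eps_pi)
  turn <- draw_turn(rng, sc$acs)
  acsv <- acs_output(world$heading, turn, mot_a[["ACSon"]])

  ## (4) arbitration
  res <- resolve_heading(lo$outputs, piv, acsv, world$heading,
                         sc$arbitration)

  ## search-timer bookkeeping
  if (lm_sum > 0 || entered) world$acs_timer <- 0L
  else if (mot_a[["ACSon"]] >= th)
    world$acs_timer <- world$acs_timer + 1L
  world$lm_sum_prev <- lm_sum

  ## (5) interventions / movement, (6) current-vector update
  displaced <- FALSE
  for (i in seq_along(sc$interventions)) {
    if (world$iv_applied[i]) next
    iv <- sc$interventions[[i]]
    hit <- (!is.null(iv$at_step) && iv$at_step == step) ||
      (!is.null(iv$on_event) &&
         any(startsWith(events, iv$on_event)))
    if (!hit) next
    world$iv_applied[i] <- TRUE
    if (iv$action == "displace") {
      world$pos <- as.numeric(iv$pos)
      if (isTRUE(iv$reset_current)) world$current <- c(0, 0)
      events <- c(events, "displaced")
      displaced <- TRUE               # passive transport: no walking
    } else if (iv$action == "set_food") {
      world$food_has[[iv$source]] <- isTRUE(iv$has_food)
    }
  }
  if (entered && sc$stop_at_home) {
    world$done <- TRUE
  } else if (!displaced && mot_a[["forage"]] >= th) {
    world$heading <- res$heading
    disp <- sc$step_length * c(cos(res$heading), sin(res$heading))
    world$pos <- world$pos + disp
    world$current <- world$current + disp   # active walking updates PI
  }

  ## (7) record
  cur_out <- pv_from_xy(world$current[1], world$current[2])
  lm_w <- res$weights[setdiff(names(res$weights), c("PI", "ACS"))]
  world$last_record <- list(
    num = c(step = step, x = world$pos[1], y = world$pos[2],
            heading = world$heading, cur_len = cur_out$length,
            cur_angle = cur_out$angle, goal_dist = d_goal_pre,
            gain = gain, timer = world$acs_timer, lm_sum = lm_sum,
            w_PI = res$weights[["PI"]], w_ACS = res$weights[["ACS"]],
            stats::setNames(mot_a, paste0("mot_", names(mot_a))),
            if (length(lm_w)) stats::setNames(lm_w,
                                              paste0("w_", names(lm_w)))),
    chr = c(winner = res$winner,
            leg = .leg_label(mot_a, th),
            events = paste(events, collapse = ";")))
  world$rng <- rng_snapshot(rng)
  world$step <- step
  world
}

#' Displace the agent (capture and release)
#'
#' Teleports the agent to a new position. Passive transport does not feed
#' the path integrator, so the current vector is preserved unless
#' `reset_current = TRUE` (the "zero-vector" manipulation: the released
#' agent behaves as if it had just left the nest).
#'
#' @param world an `antnav_world`.
#' @param new_pos release position `c(x, y)`.
#' @param reset_current zero the current vector on release.
#' @return the updated world.
#' @export
displace <- function(world, new_pos, reset_current = FALSE) {
  stopifnot(inherits(world, "antnav_world"), length(new_pos) == 2L)
  world$pos <- as.numeric(new_pos)
  if (isTRUE(reset_current)) world$current <- c(0, 0)
  world
}

.assemble_log <- function(records, sc, init_row) {
  if (length(records) == 0L) {
    log <- init_row
  } else {
    nums <- do.call(rbind, lapply(records, `[[`, "num"))
    chrs <- do.call(rbind, lapply(records, `[[`, "chr"))
    log <- data.frame(nums, stringsAsFactors = FALSE)
    log$winner <- chrs[, "winner"]
    log$leg <- chrs[, "leg"]
    log$events <- chrs[, "events"]
    if (!is.null(init_row)) log <- rbind(init_row, log)
  }
  rownames(log) <- NULL
  structure(log, class = c("antnav_log", "data.frame"),
            scenario_name = sc$name)
}

#' Run a scenario to completion
#'
#' Steps the world until the terminal event (nest entry while inbound, if
#' `stop_at_home`) or `max_steps`, and returns the trajectory log: one row
#' per step with position, heading, current-vector state, search gain and
#' timer, the winning procedure, all post-inhibition weights, motivation
#' activations, and events. Deterministic given the seed.
#'
#' @param sc an [scenario()].
#' @param seed RNG seed; defaults to the scenario's.
#' @return a data.frame of class `antnav_log`; the final world state is
#'   attached as `attr(, "world")`.
#' @export
run_scenario <- function(sc, seed = NULL) {
  world <- world_init(sc, seed)
  out <- continue_run(world, sc)
  out$log
}

#' Continue a run from a (possibly checkpointed) world state
#'
#' Because the world state is a plain value, `w2 <- world` is a
#' checkpoint; `continue_run()` on the copy reproduces exactly the steps
#' an uninterrupted run would have produced.
#'
#' @param world an `antnav_world`.
#' @param sc the matching [scenario()].
#' @return a list: `log` (`antnav_log` for the steps taken, including an
#'   initial state row when starting from step 0) and `world` (final
#'   state).
#' @export
continue_run <- function(world, sc) {
  records <- vector("list", sc$max_steps - world$step)
  n <- 0L
  init_row <- NULL
  if (world$step == 0L) {
    cur0 <- pv_from_xy(world$current[1], world$current[2])
    mot_a <- world$mot$a
    lm_ids <- vapply(sc$landmarks, `[[`, "", "id")
    init_row <- data.frame(
      t(c(step = 0, x = world$pos[1], y = world$pos[2],
          heading = world$heading, cur_len = cur0$length,
          cur_angle = cur0$angle, goal_dist = NA_real_, gain = NA_real_,
          timer = 0, lm_sum = 0, w_PI = 0, w_ACS = 0,
          stats::setNames(mot_a, paste0("mot_", names(mot_a))),
          if (length(lm_ids)) stats::setNames(numeric(length(lm_ids)),
                                              paste0("w_", lm_ids)))),
      winner = "none", leg = .leg_label(mot_a, sc$gate_threshold),
      events = "", stringsAsFactors = FALSE)
  }
  while (!world$done && world$step < sc$max_steps) {
    world <- sim_step(world, sc)
    n <- n + 1L
    records[[n]] <- world$last_record
  }
  log <- .assemble_log(records[seq_len(n)], sc, init_row)
  attr(log, "world") <- world
  list(log = log, world = world)
}
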