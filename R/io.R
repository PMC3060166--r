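.lm_to_list <- function(el) {
  if (el$kind == "route") {
    list(kind = "route", id = el$id, center = as.numeric(el$center),
         radius = el$radius, local_angle = el$local_angle,
         gate_source = el$gate_source, gate_direction = el$gate_direction)
  } else {
    list(kind = "place", id = el$id, goal = as.numeric(el$goal),
         radius = el$radius,
         signposts = lapply(seq_len(3), function(i)
           as.numeric(el$signposts[i, ])),
         learned = lapply(seq_len(3), function(i)
           as.numeric(el$learned[i, ])),
         gate_source = el$gate_source,
         gate_direction = el$gate_direction)
  }
}

.lm_from_list <- function(l) {
  if (l$kind == "route") {
    route_landmark(l$id, unlist(l$center), radius = l$radius,
                   local_angle = l$local_angle,
                   gate_source = l$gate_source,
                   gate_direction = l$gate_direction)
  } else {
    place_landmark(l$id, unlist(l$goal), radius = l$radius,
                   signposts = do.call(rbind, lapply(l$signposts, unlist)),
                   learned = do.call(rbind, lapply(l$learned, unlist)),
                   gate_source = l$gate_source,
                   gate_direction = l$gate_direction)
  }
}

#' Write a scenario to a YAML file
#'
#' Human-readable, versioned scenario configuration. Network weights are
#' stored as their constructor parameters where they match the defaults
#' pattern, and the full matrix otherwise is not needed: the weight matrix
#' is rebuilt from the stored parameters.
#'
#' @param sc an [scenario()].
#' @param path output file path.
#' @return invisibly `path`.
#' @export
scenario_to_yaml <- function(sc, path) {
  stopifnot(inherits(sc, "antnav_scenario"))
  mem <- lapply(sc$memories, function(m)
    if (is.null(m)) NULL else list(angle = m$angle, length = m$length))
  l <- list(
    format = "antnav-scenario-1",
    name = sc$name,
    nest = as.numeric(sc$nest),
    food = lapply(sc$food, function(f)
      list(pos = as.numeric(f$pos), has_food = f$has_food)),
    landmarks = lapply(sc$landmarks, .lm_to_list),
    memories = mem,
    target = sc$target,
    weights = sc$weights[setdiff(names(sc$weights), "W")],
    weights_matrix = lapply(seq_len(nrow(sc$weights$W)), function(i)
      as.numeric(sc$weights$W[i, ])),
    arbitration = unclass(sc$arbitration),
    acs = unclass(sc$acs),
    agent = list(start = as.numeric(sc$agent$start),
                 heading = sc$agent$heading,
                 current = as.numeric(sc$agent$current),
                 motivation = as.list(sc$agent$motivation)),
    interventions = sc$interventions,
    eps_goal = sc$eps_goal, step_length = sc$step_length,
    eps_pi = sc$eps_pi, gate_threshold = sc$gate_threshold,
    max_steps = sc$max_steps, seed = sc$seed,
    stop_at_home = sc$stop_at_home)
  yaml::write_yaml(l, path, precision = 15L)
  invisible(path)
}

#' Read a scenario from a YAML file
#'
#' @param path a file written by [scenario_to_yaml()].
#' @return an [scenario()].
#' @export
scenario_from_yaml <- function(path) {
  l <- yaml::read_yaml(path)
  if (!identical(l$format, "antnav-scenario-1"))
    stop("not an antnav scenario file (missing/unknown format tag)")
  units <- motivation_units()
  W <- do.call(rbind, lapply(l$weights_matrix, unlist))
  dimnames(W) <- list(units, units)
  weights <- structure(c(list(W = W), l$weights),
                       class = "motivation_weights")
  memories <- reference_memories(names(l$food))
  for (id in names(l$memories)) {
    m <- l$memories[[id]]
    if (!is.null(m))
      memories[[id]] <- polar_vector(m$angle, m$length)
  }
  scenario(
    nest = unlist(l$nest),
    food = lapply(l$food, function(f)
      list(pos = unlist(f$pos), has_food = isTRUE(f$has_food))),
    landmarks = lapply(l$landmarks, .lm_from_list),
    memories = memories,
    target = l$target,
    weights = weights,
    arbitration = do.call(arbitration_config, l$arbitration),
    acs = do.call(acs_config, l$acs),
    agent = list(start = unlist(l$agent$start),
                 heading = l$agent$heading,
                 current = unlist(l$agent$current),
                 motivation = unlist(l$agent$motivation)),
    interventions = lapply(l$interventions, function(iv) {
      if (!is.null(iv$pos)) iv$pos <- unlist(iv$pos)
      iv
    }),
    eps_goal = l$eps_goal, step_length = l$step_length,
    eps_pi = l$eps_pi, gate_threshold = l$gate_threshold,
    max_steps = l$max_steps, seed = l$seed,
    stop_at_home = isTRUE(l$stop_at_home),
    name = l$name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trajectory log to a delimited file
#'
#' Tab-separated, one row per step, with a small `#`-prefixed metadata
#' header (scenario name, number of steps).
#'
#' @param log an `antnav_log`.
#' @param path output file path.
#' @return invisibly `path`.
#' @export
write_trajectory <- function(log, path) {
  stopifnot(inherits(log, "antnav_log"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# antnav trajectory; scenario: %s; steps: %d",
                     attr(log, "scenario_name") %||% "unknown",
                     max(log$step)), con)
  utils::write.table(as.data.frame(log), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory log written by [write_trajectory()]
#'
#' @param path input file path.
#' @return an `antnav_log` data.frame.
#' @export
read_trajectory <- function(path) {
  log <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  log$events[is.na(log$events)] <- ""
  structure(log, class = c("antnav_log", "data.frame"))
}
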