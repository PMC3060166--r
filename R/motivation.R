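#' Names of the eight motivation units
#'
#' The recurrent selection network consists of four mutually inhibitory
#' pairs: `stay`/`forage` (top-level behaviour), `sourceA`/`sourceB` (which
#' food source is the goal), `outbound`/`inbound` (trip direction), and
#' `ACSon`/`ACSoff` (whether the search generator may contribute). `forage`
#' excites all six lower units and receives weak excitation back from them.
#'
#' @return character vector of unit names, in canonical order.
#' @export
motivation_units <- function() {
  c("stay", "forage", "sourceA", "sourceB",
    "outbound", "inbound", "ACSon", "ACSoff")
}

.mot_pairs <- function() {
  list(c("stay", "forage"), c("sourceA", "sourceB"),
       c("outbound", "inbound"), c("ACSon", "ACSoff"))
}

#' Default motivation-network weights
#'
#' Builds the connection matrix `W` used by [motivation_step()], where the
#' update is `a' = clip01(W %*% a + drive)`. Defaults:
#' * self-excitation +1.0 on the six persistent units, which makes a won
#'   decision self-sustaining after the driving stimulus is gone;
#' * no self-excitation on `ACSon`/`ACSoff`, which are sensor-following
#'   gating units (search must stop when its drive disappears);
#' * mutual pair inhibition -1.2, stronger than self-coupling so each pair
#'   relaxes to a single winner;
#' * `forage` -> each lower unit +0.3 and each lower unit -> `forage` +0.1.
#'
#' All values are free parameters of the scenario configuration.
#'
#' @param self self-excitation of persistent units.
#' @param inhibition pair inhibition magnitude (entered as negative weight).
#' @param forage_drive excitation from `forage` to its six children.
#' @param child_feedback excitation from each child back to `forage`.
#' @param acs_self self-excitation of the `ACSon`/`ACSoff` pair.
#' @param habituation logical: make the inhibitory connections habituate
#'   (the oscillation variant; see [motivation_step()]).
#' @param hab_alpha,hab_beta habituation growth and recovery rates.
#' @param child_self self-excitation of the four goal/direction units
#'   (`sourceA/B`, `outbound/inbound`): below 1, so that a decision decays
#'   once `forage` stops backing it, yet `child_self + forage_drive >= 1`
#'   keeps a won decision latched while foraging continues.
#' @param acs_off_gain multiplier applied to the summed landmark salience
#'   before it drives `ACSoff` (see [event_drives()]).
#' @param relax_rate damping of the synchronous update in `(0, 1]`:
#'   `a' = (1 - r) a + r clip01(W a + drive)`. Damping leaves every fixed
#'   point unchanged but prevents the period-2 flip-flop that an undamped
#'   synchronous update of a mutually inhibitory pair can fall into.
#' @return a list of class `motivation_weights` with the matrix `W` and the
#'   habituation settings.
#' @export
default_motivation_weights <- function(self = 1.0, inhibition = 1.2,
                                       forage_drive = 0.3,
                                       child_feedback = 0.1,
                                       child_self = 0.8,
                                       acs_self = 0.0,
                                       habituation = FALSE,
                                       hab_alpha = 0.03, hab_beta = 0.03,
                                       acs_off_gain = 2.0,
                                       relax_rate = 0.5) {
  stopifnot(relax_rate > 0, relax_rate <= 1)
  units <- motivation_units()
  n <- length(units)
  W <- matrix(0, n, n, dimnames = list(units, units))
  diag(W) <- self
  for (u in c("sourceA", "sourceB", "outbound", "inbound"))
    W[u, u] <- child_self
  W["ACSon", "ACSon"] <- acs_self
  W["ACSoff", "ACSoff"] <- acs_self
  for (p in .mot_pairs()) {
    W[p[1], p[2]] <- -inhibition
    W[p[2], p[1]] <- -inhibition
  }
  children <- setdiff(units, c("stay", "forage"))
  W[children, "forage"] <- forage_drive
  W["forage", children] <- child_feedback
  structure(list(W = W, habituation = habituation,
                 hab_alpha = hab_alpha, hab_beta = hab_beta,
                 acs_off_gain = acs_off_gain, relax_rate = relax_rate),
            class = "motivation_weights")
}

#' Create a motivation state
#'
#' @param init named numeric vector of initial activations in `[0, 1]`;
#'   unnamed units start at 0.
#' @return a list of class `motivation_state` with fields `a` (named
#'   activations) and `h` (habituation levels per connection, all 0).
#' @export
motivation_state <- function(init = c(forage = 1)) {
  units <- motivation_units()
  a <- stats::setNames(numeric(length(units)), units)
  if (length(init)) {
    stopifnot(all(names(init) %in% units))
    a[names(init)] <- pmin(1, pmax(0, init))
  }
  h <- matrix(0, length(units), length(units),
              dimnames = list(units, units))
  structure(list(a = a, h = h), class = "motivation_state")
}

.clip01 <- function(x) pmin(1, pmax(0, x))

#' One synchronous update of the motivation network
#'
#' `a' = (1 - r) a + r clip01(W_eff %*% a + drive)` with damping factor
#' `r = relax_rate`; all activations stay in `[0, 1]`.
#' With habituation enabled, every inhibitory weight `W[i, j]` is scaled by
#' `1 - h[i, j]` and the habituation level of each inhibitory connection
#' grows with its presynaptic activity and recovers slowly:
#' `h' = h + alpha * a_pre * (1 - h) - beta * h`. Habituating inhibition
#' makes a pair whose two units are both driven alternate its winner
#' instead of settling.
#'
#' @param state a [motivation_state()].
#' @param weights a [default_motivation_weights()] object.
#' @param drives named numeric vector of additive drive terms (missing
#'   units mean zero drive).
#' @return the updated [motivation_state()].
#' @export
motivation_step <- function(state, weights, drives = numeric(0)) {
  stopifnot(inherits(state, "motivation_state"),
            inherits(weights, "motivation_weights"))
  units <- motivation_units()
  d <- stats::setNames(numeric(length(units)), units)
  if (length(drives)) {
    stopifnot(all(names(drives) %in% units))
    d[names(drives)] <- drives
  }
  W <- weights$W
  r <- if (is.null(weights$relax_rate)) 1 else weights$relax_rate
  if (isTRUE(weights$habituation)) {
    inh <- W < 0
    W_eff <- W
    W_eff[inh] <- W[inh] * (1 - state$h[inh])
    a_new <- (1 - r) * state$a + r * .clip01(as.vector(W_eff %*% state$a) + d)
    h <- state$h
    pre <- matrix(rep(state$a, each = length(units)),
                  length(units), length(units),
                  dimnames = dimnames(h))
    h[inh] <- h[inh] + weights$hab_alpha * pre[inh] * (1 - h[inh]) -
      weights$hab_beta * h[inh]
    h <- pmin(1, pmax(0, h))
    state$h <- h
  } else {
    a_new <- (1 - r) * state$a + r * .clip01(as.vector(W %*% state$a) + d)
  }
  state$a <- stats::setNames(as.vector(a_new), units)
  state
}

#' Relax the motivation network to an attractor
#'
#' Iterates [motivation_step()] under constant drives until the largest
#' activation change falls below `tol` or `max_iters` is reached. The
#' returned `converged` flag reports numeric convergence; `tied` flags
#' pairs that ended in an exact tie with both units active (a symmetric
#' fixed point, i.e. no behavioural decision). With habituation enabled and
#' both units of a pair driven, the network does not converge: activations
#' oscillate.
#'
#' @param state a [motivation_state()].
#' @param weights a [default_motivation_weights()] object.
#' @param drives named numeric drive vector, held constant while relaxing.
#' @param tol convergence tolerance on the activation change.
#' @param max_iters iteration cap.
#' @return a list: `state` (relaxed [motivation_state()]), `converged`
#'   (logical), `iterations`, `tied` (character vector of tied pair labels).
#' @export
relax_motivation <- function(state, weights, drives = numeric(0),
                             tol = 1e-6, max_iters = 200L) {
  stopifnot(tol > 0)
  converged <- FALSE
  it <- 0L
  while (it < max_iters) {
    it <- it + 1L
    new <- motivation_step(state, weights, drives)
    delta <- max(abs(new$a - state$a))
    if (isTRUE(weights$habituation))  # a state is only stable if the
      delta <- max(delta, abs(new$h - state$h))  # habituation is, too
    state <- new
    if (delta < tol) { converged <- TRUE; break }
  }
  tied <- character(0)
  for (p in .mot_pairs()) {
    if (abs(state$a[[p[1]]] - state$a[[p[2]]]) < 10 * tol &&
        state$a[[p[1]]] > tol)
      tied <- c(tied, paste(p, collapse = "/"))
  }
  list(state = state, converged = converged, iterations = it, tied = tied)
}

#' Map behavioural events and continuous signals to motivation drives
#'
#' Discrete events: `"left_nest"` drives `outbound`; `"food_found"` drives
#' `inbound`; `"food_absent:<id>"` applies a negative drive to the active
#' source unit (the disappointed goal), which lets the rival source win the
#' pair; `"entered_nest"` drives `stay`. Continuous signals: the summed
#' salience of all active landmark elements drives `ACSoff` (scaled by
#' `acs_off_gain` so a single fresh landmark reliably shuts search off),
#' and the search gain drives `ACSon`. `forage` excitation of both search
#' units is part of the weight matrix, not of the drives.
#'
#' @param events character vector of event codes (see above); unknown codes
#'   are an error.
#' @param landmark_sum summed salience of all landmark elements.
#' @param acs_gain current value of the search gain function, in `[0, 1]`.
#' @param acs_off_gain multiplier on `landmark_sum` for the `ACSoff` drive.
#' @return named numeric drive vector over all units.
#' @export
event_drives <- function(events = character(0), landmark_sum = 0,
                         acs_gain = 0, acs_off_gain = 2.0) {
  units <- motivation_units()
  d <- stats::setNames(numeric(length(units)), units)
  for (ev in events) {
    code <- strsplit(ev, ":", fixed = TRUE)[[1]]
    switch(code[1],
      left_nest    = { d[["outbound"]] <- d[["outbound"]] + 1 },
      food_found   = { d[["inbound"]] <- d[["inbound"]] + 1 },
      food_absent  = {
        if (length(code) < 2L) stop("food_absent event needs a source id")
        unit <- paste0("source", code[2])
        if (!unit %in% units) stop(sprintf("unknown source '%s'", code[2]))
        d[[unit]] <- d[[unit]] - 1
      },
      entered_nest = { d[["stay"]] <- d[["stay"]] + 1 },
      displaced    = { },
      stop(sprintf("unknown event '%s'", ev))
    )
  }
  d[["ACSoff"]] <- d[["ACSoff"]] + acs_off_gain * landmark_sum
  d[["ACSon"]] <- d[["ACSon"]] + acs_gain
  d
}
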