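# Shared fixtures and independent mini-oracles for the test suite.
# Everything is built in code; no stored data.

# Independent, minimal reimplementation of the damped clipped-linear
# relaxation, used as an oracle for the packaged motivation dynamics.
iterate_motnet_oracle <- function(a, W, drive, rate, n_iter = 500) {
  clip <- function(x) pmin(1, pmax(0, x))
  for (i in seq_len(n_iter))
    a <- (1 - rate) * a + rate * clip(as.vector(W %*% a) + drive)
  a
}

# A forager state with a fully decided motivation attractor.
decided_forager <- function(target = "A", direction = "outbound") {
  motivation_state(stats::setNames(
    c(1, 1, 1), c("forage", paste0("source", target), direction)))
}

# Minimal one-landmark world for guidance micro-simulations.
walk_with_place_landmark <- function(start, element, n_steps,
                                     step_length = 10) {
  pos <- start
  path <- matrix(NA_real_, n_steps + 1, 2)
  path[1, ] <- pos
  for (i in seq_len(n_steps)) {
    out <- snapshot_output(element, pos)
    if (out$length == 0) {
      path <- path[seq_len(i), , drop = FALSE]
      break
    }
    pos <- pos + step_length * c(cos(out$angle), sin(out$angle))
    path[i + 1, ] <- pos
  }
  path[!is.na(path[, 1]), , drop = FALSE]
}

# Normalize a log for exact comparison (drop attributes and row names).
strip_log <- function(l) {
  l <- as.data.frame(l)
  attr(l, "scenario_name") <- NULL
  attr(l, "world") <- NULL
  rownames(l) <- NULL
  l
}

# Per-row flag: did the agent actively walk into this row's position?
# (False for the terminal nest-entry step and for passive transport.)
walked <- function(log) {
  !grepl("entered_nest|displaced", log$events)
}

# Largest distance from the nest->goal line (cross-track error).
cross_track <- function(x, y, from, to) {
  u <- (to - from) / sqrt(sum((to - from)^2))
  abs((x - from[1]) * u[2] - (y - from[2]) * u[1])
}

# Outer search-gain breakpoint for each logged step, from the logged
# searching timer (defaults of acs_config()).
d2_of <- function(timer, cfg = acs_config()) {
  cfg$d2_0 + (cfg$d2_max - cfg$d2_0) * pmin(timer / cfg$t_max, 1)
}
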