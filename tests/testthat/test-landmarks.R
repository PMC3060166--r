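test_that("route salience follows the stepwise forgetting schedule", {
  expect_identical(route_salience(0), 1.0)
  expect_equal(route_salience(1), 0.95)
  expect_equal(route_salience(10), 0.5)
  expect_equal(route_salience(12), 0.5)
  expect_equal(route_salience(15), 0.5)
  expect_identical(route_salience(16), 0.0)
  expect_identical(route_salience(100), 0.0)
  expect_error(route_salience(-1), "non-negative")
  # monotone non-increasing, support exactly steps 0..15
  s <- route_salience(0:30)
  expect_true(all(diff(s) <= 0))
  expect_true(all(s[1:16] > 0))
  expect_true(all(s[17:31] == 0))
})

test_that("route landmarks trigger only inside the catchment with both gates passing", {
  el <- route_landmark("r1", c(100, 0), radius = 20, local_angle = pi / 2,
                       gate_source = "A", gate_direction = "outbound")
  mot_ok <- decided_forager("A", "outbound")$a
  mot_in <- decided_forager("A", "inbound")$a
  mot_b <- decided_forager("B", "outbound")$a
  # inside + gates pass: trigger
  expect_identical(route_trigger(el, c(90, 0), mot_ok), 0L)
  # wrong trip direction: the stimulus is ignored entirely
  expect_identical(route_trigger(el, c(90, 0), mot_in), NA_integer_)
  # wrong goal source: ignored too
  expect_identical(route_trigger(el, c(90, 0), mot_b), NA_integer_)
  # outside: inactive counter stays inactive, active counter decays
  expect_identical(route_trigger(el, c(500, 0), mot_ok), NA_integer_)
  expect_identical(route_trigger(el, c(500, 0), mot_ok, 3L), 4L)
  # re-entry retriggers (counter resets to 0)
  expect_identical(route_trigger(el, c(95, 5), mot_ok, 9L), 0L)
  # decayed-out counters deactivate
  expect_identical(route_trigger(el, c(500, 0), mot_ok, 15L), NA_integer_)
})

test_that("snapshot matching points at the goal and vanishes on arrival", {
  el <- place_landmark("h", goal = c(0, 0), radius = 25,
                       gate_direction = "inbound")
  # at the goal: corrections cancel
  expect_equal(snapshot_output(el, c(0, 0))$length, 0)
  # displaced: output is the bearing back to the goal, unit length
  out <- snapshot_output(el, c(10, 0))
  expect_equal(out$length, 1)
  expect_equal(out$angle, pi, tolerance = 1e-9)
  # agreement with the direct bearing for arbitrary displacements
  rng <- rng_stream(9)
  for (i in 1:20) {
    p <- rng_uniform(rng, 2, -25, 25)
    if (sqrt(sum(p^2)) < 2) next
    out <- snapshot_output(el, p)
    expect_equal(out$angle, angle_between(p, c(0, 0)), tolerance = 1e-9)
  }
  # symmetric signposts, agent on the symmetry axis: output on the axis
  sym <- place_landmark("s", goal = c(0, 0),
                        signposts = rbind(c(60, 0), c(-30, 52), c(-30, -52)),
                        gate_direction = "inbound")
  out <- snapshot_output(sym, c(-20, 0))
  expect_equal(out$angle, 0, tolerance = 1e-9)
})

test_that("memory elements are independent: one element's memory never leaks into another", {
  e1 <- route_landmark("r1", c(100, 0), local_angle = 0.3,
                       gate_source = "A", gate_direction = "outbound")
  e2 <- route_landmark("r2", c(300, 0), local_angle = -1.1,
                       gate_source = "A", gate_direction = "outbound")
  mot <- decided_forager("A", "outbound")$a
  counters <- c(r1 = 0L, r2 = 5L)
  base <- landmark_outputs(list(e1, e2), counters, c(100, 0), mot)
  e1_mut <- route_landmark("r1", c(100, 0), local_angle = 2.9,
                           gate_source = "A", gate_direction = "outbound")
  mut <- landmark_outputs(list(e1_mut, e2), counters, c(100, 0), mot)
  expect_identical(base$outputs[base$outputs$id == "r2", ],
                   mut$outputs[mut$outputs$id == "r2", ])
})

test_that("a place landmark guides the agent into the goal", {
  el <- place_landmark("h", goal = c(0, 0), radius = 25,
                       gate_direction = "inbound")
  rng <- rng_stream(31)
  budget <- ceiling(3 * el$radius / 10)
  for (i in 1:10) {
    ang <- rng_uniform(rng, 1, -pi, pi)
    r <- rng_uniform(rng, 1, 12, 25)
    start <- r * c(cos(ang), sin(ang))
    path <- walk_with_place_landmark(start, el, budget)
    final <- path[nrow(path), ]
    expect_lt(sqrt(sum(final^2)), 10)       # within one step of the goal
    expect_lte(nrow(path) - 1, budget)
  }
})

test_that("a route landmark repels: the agent leaves along the local vector", {
  el <- route_landmark("r", c(0, 0), radius = 20, local_angle = 0.7,
                       gate_source = "A", gate_direction = "outbound")
  mot <- decided_forager("A", "outbound")$a
  pos <- c(-5, 0)
  counters <- c(r = NA_integer_)
  for (i in 1:6) {
    lo <- landmark_outputs(list(el), counters, pos, mot)
    counters <- lo$counters
    out <- lo$outputs
    expect_gt(out$salience, 0)
    pos <- pos + 10 * c(cos(out$angle), sin(out$angle))
  }
  # left the catchment along the stored direction
  expect_gt(dist_xy(pos, el$center), el$radius)
  expect_equal(angle_between(c(-5, 0), pos), 0.7, tolerance = 1e-6)
})
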