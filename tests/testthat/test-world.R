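test_that("without landmarks the agent walks a straight line out and back", {
  sc <- scenario(food = list(A = list(pos = c(350, 250), has_food = TRUE)),
                 landmarks = list(), max_steps = 300L, name = "bare")
  log <- run_scenario(sc)
  w <- attr(log, "world")
  expect_true(w$done)
  expect_true("food_found" %in% unlist(strsplit(log$events, ";")))
  # outbound leg collinear with nest->A (excluding the final approach,
  # where the nearing goal lets a little search gain blend in)
  out_leg <- log[log$leg == "outbound" & log$step > 0, ]
  ct <- cross_track(out_leg$x, out_leg$y, c(0, 0), c(350, 250))
  expect_lt(max(head(ct, -2)), 1e-6)
  # terminal closure: back inside the nest radius, current vector reset
  expect_lte(dist_xy(c(log$x[nrow(log)], log$y[nrow(log)]), c(0, 0)),
             sc$eps_goal)
  expect_equal(log$cur_len[nrow(log)], 0)
})

test_that("every active step displaces the agent by exactly the step length", {
  for (sc in list(scenario_route_trip("A"), scenario_shortcut(),
                  scenario_search(max_steps = 300L))) {
    log <- run_scenario(sc)
    d <- sqrt(diff(log$x)^2 + diff(log$y)^2)
    w <- walked(log)[-1]
    expect_equal(d[w], rep(10, sum(w)), tolerance = 1e-9)
  }
})

test_that("runs are deterministic given the seed", {
  sc <- scenario_search(max_steps = 300L)
  expect_identical(as.data.frame(run_scenario(sc, seed = 7)),
                   as.data.frame(run_scenario(sc, seed = 7)))
  l1 <- run_scenario(sc, seed = 7)
  l2 <- run_scenario(sc, seed = 8)
  expect_false(identical(l1$x, l2$x))
})

test_that("a checkpointed world resumes bit-for-bit", {
  sc <- scenario_displaced_forager()
  w <- world_init(sc)
  for (i in 1:120) w <- sim_step(w, sc)
  chk <- w                                 # plain-value checkpoint
  resumed <- continue_run(chk, sc)
  full <- run_scenario(sc)
  expect_identical(strip_log(resumed$log),
                   strip_log(full[full$step > 120, ]))
})

test_that("displacement semantics: passive transport vs zero-vector release", {
  sc <- scenario_route_trip("A")
  w <- world_init(sc)
  for (i in 1:20) w <- sim_step(w, sc)
  cur_before <- w$current
  moved <- displace(w, c(999, 999))          # passive transport
  expect_equal(moved$pos, c(999, 999))
  expect_identical(moved$current, cur_before)
  zeroed <- displace(w, c(999, 999), reset_current = TRUE)
  expect_equal(zeroed$current, c(0, 0))
  same <- displace(w, w$pos)                 # no-op displacement
  expect_identical(same$pos, w$pos)
  expect_identical(same$current, w$current)
})

test_that("all canonical scenarios terminate at the nest with a reset integrator", {
  scs <- list(scenario_route_trip("A"), scenario_route_trip("B"),
              scenario_shortcut(), scenario_displaced_forager())
  for (sc in scs) {
    log <- run_scenario(sc)
    w <- attr(log, "world")
    expect_true(w$done)
    expect_lte(dist_xy(w$pos, sc$nest), sc$eps_goal)
    expect_lt(log$cur_len[nrow(log)], sc$eps_goal)
  }
})

test_that("randomized scenarios validate and complete their trips", {
  for (s in 1:5) {
    sc <- random_scenario(s)
    expect_true(validate_scenario(sc))
    log <- run_scenario(sc)
    w <- attr(log, "world")
    expect_true(w$done)
    expect_lte(dist_xy(w$pos, sc$nest), sc$eps_goal)
  }
})

test_that("scenario validation rejects malformed worlds", {
  expect_error(scenario(food = list(C = list(pos = c(1, 1),
                                             has_food = TRUE))),
               "A.*B|ids")
  expect_error(
    scenario(landmarks = list(
      route_landmark("x", c(1, 1), local_angle = 0,
                     gate_source = "B", gate_direction = "outbound"))),
    "unknown source")
  expect_error(
    scenario(landmarks = list(
      route_landmark("x", c(1, 1), local_angle = 0,
                     gate_source = "A", gate_direction = "outbound"),
      route_landmark("x", c(2, 2), local_angle = 0,
                     gate_source = "A", gate_direction = "outbound"))),
    "unique")
  expect_error(scenario(interventions = list(list(action = "explode"))),
               "unknown intervention")
})

test_that("direction-gated memories never cross legs in a full run", {
  log <- run_scenario(scenario_route_trip("A"))
  out_cols <- grep("^w_rA_out", names(log), value = TRUE)
  in_cols <- grep("^w_rA_in", names(log), value = TRUE)
  inb <- log$leg == "inbound"
  expect_true(all(as.matrix(log[inb, out_cols]) == 0))
  outb <- log$leg == "outbound"
  expect_true(all(as.matrix(log[outb, in_cols]) == 0))
})
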