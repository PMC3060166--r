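test_that("motivation dynamics agree with an independent relaxation oracle", {
  w <- default_motivation_weights()
  st <- motivation_state(c(forage = 1, sourceA = 0.4, sourceB = 0.3))
  drives <- stats::setNames(numeric(8), motivation_units())
  drives[["outbound"]] <- 0.6
  oracle <- iterate_motnet_oracle(st$a, w$W, drives, w$relax_rate)
  got <- relax_motivation(st, w, drives, max_iters = 500)
  expect_true(got$converged)
  expect_equal(unname(got$state$a), unname(oracle), tolerance = 1e-4)
})

test_that("a decided attractor persists without drive", {
  w <- default_motivation_weights()
  st <- decided_forager("A", "outbound")
  out <- relax_motivation(st, w)
  expect_true(out$converged)
  expect_equal(out$state$a[["forage"]], 1)
  expect_equal(out$state$a[["stay"]], 0)
  expect_equal(out$state$a[["sourceA"]], 1)
  expect_equal(out$state$a[["sourceB"]], 0)
  expect_equal(out$state$a[["outbound"]], 1)
})

test_that("the favoured unit of a pair wins and the rival is silenced", {
  w <- default_motivation_weights()
  st <- motivation_state(c(forage = 1))
  drives <- c(sourceA = 0.501, sourceB = 0.5)
  out <- relax_motivation(st, w, drives, max_iters = 500)
  expect_true(out$converged)
  expect_gt(out$state$a[["sourceA"]], 0.9)
  expect_lt(out$state$a[["sourceB"]], 0.1)
})

test_that("strong stay drive shuts down forage and all its children", {
  w <- default_motivation_weights()
  st <- decided_forager("A", "outbound")
  out <- relax_motivation(st, w, c(stay = 2), max_iters = 500)
  expect_true(out$converged)
  expect_gt(out$state$a[["stay"]], 0.9)
  expect_lt(out$state$a[["forage"]], 0.1)
  for (u in c("sourceA", "sourceB", "outbound", "inbound"))
    expect_lt(out$state$a[[u]], 0.1)
})

test_that("an exactly symmetric drive is flagged as a tie, asymmetric starts resolve", {
  w <- default_motivation_weights()
  st <- motivation_state(c(forage = 1))
  sym <- relax_motivation(st, w, c(sourceA = 0.5, sourceB = 0.5),
                          max_iters = 500)
  expect_true("sourceA/sourceB" %in% sym$tied)

  rng <- rng_stream(23)
  for (i in 1:100) {
    init <- rng_uniform(rng, 8)
    names(init) <- motivation_units()
    init["forage"] <- 1; init["stay"] <- 0
    # event-magnitude favourite drive: strong enough to overturn an
    # entrenched (latched) rival decision
    dA <- rng_uniform(rng, 1, 1, 1.5)
    dB <- rng_uniform(rng, 1, 0, 0.4)
    out <- relax_motivation(motivation_state(init), w,
                            c(sourceA = dA, sourceB = dB),
                            max_iters = 500)
    expect_true(out$converged)
    expect_gt(out$state$a[["sourceA"]], 0.9)
    expect_lt(out$state$a[["sourceB"]], 0.1)
    expect_false("sourceA/sourceB" %in% out$tied)
  }
})

test_that("activations stay in [0, 1] under arbitrary drive sequences", {
  w <- default_motivation_weights()
  rng <- rng_stream(4)
  st <- motivation_state()
  for (i in 1:300) {
    drives <- stats::setNames(rng_uniform(rng, 8, -3, 3),
                              motivation_units())
    st <- motivation_step(st, w, drives)
    expect_true(all(st$a >= 0 & st$a <= 1))
  }
})

test_that("event mapping drives the documented units", {
  d <- event_drives("left_nest")
  expect_equal(d[["outbound"]], 1)
  d <- event_drives("food_found")
  expect_equal(d[["inbound"]], 1)
  d <- event_drives("food_absent:A")
  expect_equal(d[["sourceA"]], -1)
  d <- event_drives(character(0), landmark_sum = 1.5, acs_gain = 0.7,
                    acs_off_gain = 2)
  expect_equal(d[["ACSoff"]], 3)
  expect_equal(d[["ACSon"]], 0.7)
  expect_equal(sum(abs(event_drives(character(0)))), 0)
  expect_error(event_drives("teleport"), "unknown event")
})

test_that("a failed food visit hands the goal to the rival source", {
  w <- default_motivation_weights()
  st <- decided_forager("A", "outbound")
  out <- relax_motivation(st, w, event_drives("food_absent:A"),
                          max_iters = 500)
  expect_true(out$converged)
  expect_lt(out$state$a[["sourceA"]], 0.1)
  expect_gt(out$state$a[["sourceB"]], 0.9)
  expect_gt(out$state$a[["outbound"]], 0.9)  # still outbound
})

test_that("summed landmark salience switches the search pair off", {
  w <- default_motivation_weights()
  st <- decided_forager("A", "inbound")
  st$a[["ACSon"]] <- 1   # searching when the landmark appears
  out <- relax_motivation(st, w, event_drives(landmark_sum = 2),
                          max_iters = 500)
  expect_gt(out$state$a[["ACSoff"]], 0.5)
  expect_lt(out$state$a[["ACSon"]], 0.5)
  # ... and a full search gain wins it back once landmarks are gone
  out2 <- relax_motivation(out$state, w, event_drives(acs_gain = 1),
                           max_iters = 500)
  expect_gt(out2$state$a[["ACSon"]], 0.9)
})

test_that("habituating inhibition makes a doubly driven pair oscillate", {
  w <- default_motivation_weights(habituation = TRUE)
  st <- motivation_state(c(forage = 1, outbound = 1))
  drives <- c(outbound = 0.5, inbound = 0.5)
  diff_sign <- numeric(200)
  for (i in 1:200) {
    st <- motivation_step(st, w, drives)
    diff_sign[i] <- sign(st$a[["inbound"]] - st$a[["outbound"]])
  }
  flips <- sum(diff(diff_sign[diff_sign != 0]) != 0)
  expect_gte(flips, 2)
  # and relax() reports the non-convergence
  rel <- relax_motivation(motivation_state(c(forage = 1, outbound = 1)),
                          w, drives, max_iters = 300)
  expect_false(rel$converged)
})
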