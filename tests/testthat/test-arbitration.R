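test_that("lateral inhibition picks a single winner among unequal route landmarks", {
  out <- lateral_inhibit(c(new = 1.0, old = 0.4), c("route", "route"))
  expect_equal(out[["new"]], 0.84)   # 1 - 0.4 * 0.4
  expect_equal(out[["old"]], 0)     # 0.4 - 0.4 * 1 rectified
})

test_that("place landmarks outweigh route landmarks via asymmetric edges", {
  out <- lateral_inhibit(c(p = 1.0, r = 1.0), c("place", "route"))
  expect_equal(out[["p"]], 1.0)     # no route -> place edge
  expect_equal(out[["r"]], 0.6)
})

test_that("close competitors in the PI/search pool blend instead of resolving", {
  out <- lateral_inhibit(c(PI = 0.2, ACS = 0.2), c("pi", "acs"))
  expect_equal(unname(out), c(0.12, 0.12))
})

test_that("any active landmark zeroes the path integrator's salience", {
  expect_equal(suppress_pi(1.0, 1.0), 0)
  expect_equal(suppress_pi(0, 0.37), 0.37)
  expect_equal(suppress_pi(0.5, 1.0), 0)   # even a decayed landmark
})

test_that("the winner-dominance threshold sits at a 2.5-fold salience ratio", {
  rng <- rng_stream(17)
  for (i in 1:50) {
    s1 <- rng_uniform(rng, 1, 0.2, 1)
    ratio <- rng_uniform(rng, 1, 2.6, 6)
    out <- lateral_inhibit(c(a = s1, b = s1 / ratio), c("route", "route"))
    expect_gt(out[["a"]], 0)
    expect_equal(out[["b"]], 0)
    close <- lateral_inhibit(c(a = s1, b = s1 / 2.4), c("route", "route"))
    expect_gt(close[["b"]], 0)     # below 2.5x both survive
  }
})

test_that("post-inhibition weights are never negative", {
  rng <- rng_stream(3)
  kinds <- c("route", "route", "route", "place", "place")
  for (i in 1:50) {
    s <- rng_uniform(rng, 5, 0, 2)
    expect_true(all(lateral_inhibit(s, kinds) >= 0))
  }
})

test_that("resolved headings honour suppression and scaling", {
  cfg <- arbitration_config()
  no_lm <- data.frame(id = character(0), kind = character(0),
                      angle = numeric(0), salience = numeric(0))
  # only the integrator active: heading is its angle, weight 0.2
  r <- resolve_heading(no_lm, polar_vector(pi / 4, 1),
                       polar_vector(0, 0), prev_heading = 0, cfg)
  expect_equal(r$heading, pi / 4)
  expect_equal(r$pre[["PI"]], 0.2)
  expect_equal(r$winner, "PI")
  # an active route landmark overrides an opposing integrator entirely
  lm <- data.frame(id = "r1", kind = "route", angle = 0, salience = 1)
  r <- resolve_heading(lm, polar_vector(pi, 1), polar_vector(0, 0), 0, cfg)
  expect_equal(r$heading, 0)
  expect_equal(r$weights[["PI"]], 0)
  # zero-vector state: integrator silent, random turn governs
  r <- resolve_heading(no_lm, polar_vector(0, 0),
                       polar_vector(0.45, 1), prev_heading = 0, cfg)
  expect_equal(r$heading, 0.45)
  expect_equal(r$winner, "ACS")
  # nothing active at all: previous heading kept
  r <- resolve_heading(no_lm, polar_vector(0, 0), polar_vector(1, 0),
                       prev_heading = 0.8, cfg)
  expect_equal(r$heading, 0.8)
  expect_equal(r$winner, "none")
})

test_that("the search motivation reciprocally gates the integrator", {
  cfg <- arbitration_config()
  no_lm <- data.frame(id = character(0), kind = character(0),
                      angle = numeric(0), salience = numeric(0))
  # full search activation silences the integrator
  r <- resolve_heading(no_lm, polar_vector(0, 1), polar_vector(1, 1), 0, cfg)
  expect_equal(r$pre[["PI"]], 0)
  # partial activation blends
  r <- resolve_heading(no_lm, polar_vector(0, 1),
                       polar_vector(1, 0.5), 0, cfg)
  expect_equal(r$pre[["PI"]], 0.2 * 0.5)
})

test_that("headings are invariant under uniform scaling of a pool's saliences", {
  cfg <- arbitration_config()
  lm <- data.frame(id = c("r1", "r2"), kind = c("route", "route"),
                   angle = c(0.2, 1.1), salience = c(0.9, 0.5))
  zero_pi <- polar_vector(0, 0); zero_acs <- polar_vector(0, 0)
  h1 <- resolve_heading(lm, zero_pi, zero_acs, 0, cfg)$heading
  lm$salience <- lm$salience * 3.7
  h2 <- resolve_heading(lm, zero_pi, zero_acs, 0, cfg)$heading
  expect_equal(h1, h2, tolerance = 1e-12)
})
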