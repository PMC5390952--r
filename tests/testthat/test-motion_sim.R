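test_that("trajectory archetypes have their stated structure", {
  for (seed in c(1, 7)) {
    st <- generate_trajectory("stable", 120, 25, seed = seed)
    expect_lte(max(abs(trackdose:::traj_matrix(st))), 1)

    cd <- generate_trajectory("continuous_drift", 300, 25, seed = seed)
    n <- nrow(cd)
    expect_lt(cd$d_ap_mm[n], 0) # posterior
    expect_lt(cd$d_si_mm[n], 0) # inferior

    hf <- generate_trajectory("high_frequency", 300, 25, seed = seed)
    expect_gt(mean(hf$d_ap_mm[hf$t_s > 150]), 0) # anterior on average
  }
  # erratic transients push anteriorly beyond the drift baseline
  er <- generate_trajectory("erratic", 300, 25, seed = 2)
  drift <- trajectory_params("erratic")$drift_ap_mm_min * er$t_s / 60
  expect_gt(max(er$d_ap_mm - drift), 1)
  expect_error(generate_trajectory("sideways", 10), "archetype")
  expect_error(generate_trajectory("stable", -1), "duration")
})

test_that("trajectories are bit-reproducible per seed and uniform in time", {
  a <- generate_trajectory("erratic", 60, 25, seed = 11)
  b <- generate_trajectory("erratic", 60, 25, seed = 11)
  expect_identical(a, b)
  c <- generate_trajectory("erratic", 60, 25, seed = 12)
  expect_false(identical(a, c))
  expect_equal(diff(a$t_s), rep(0.04, nrow(a) - 1))
  expect_error(trajectory(c(0, 0.1, 0.15), matrix(0, 3, 3)), "uniform")
  expect_error(trajectory(c(0, -0.1), matrix(0, 2, 3)), "increase")
})

test_that("nearest_target_sample matches a brute-force scan with ties", {
  traj <- generate_trajectory("stable", 20, 25, seed = 3)
  with_seed(99, {
    ts <- stats::runif(1000, -1, 21)
    for (t in ts) {
      k <- nearest_target_sample(t, traj)$index
      expect_identical(k, which.min(abs(t - traj$t_s)))
    }
  })
  # exact sample time and exact midpoint (tie -> earlier)
  tt <- c(1, 2, 3); d <- cbind(1:3, 4:6, 7:9)
  tr <- trajectory(tt, d)
  expect_equal(nearest_target_sample(2, tr)$index, 2L)
  expect_equal(nearest_target_sample(2.5, tr)$index, 2L)
})

test_that("delayed_view applies the latency model", {
  ts <- seq(0, 10, by = 0.04)
  ramp <- trajectory(ts, cbind(0, 0, ts)) # d_SI = t mm/s
  # no latency: nearest sample
  expect_equal(delayed_view(ramp, latency_model(0, 0, 1), 5.0, 1)[3], 5.0)
  # constant trajectory: latency invisible
  const <- trajectory(ts, matrix(rep(c(1, 2, 3), each = length(ts)),
                                 ncol = 3))
  expect_equal(delayed_view(const, latency_model(100, 15, 5), 5.0, 2),
               c(1, 2, 3))
  # 100 ms deterministic latency on the ramp
  got <- delayed_view(ramp, latency_model(100, 0, 1), 5.0, 3)[3]
  expect_lt(abs(got - 4.9), 0.04 + 1e-12)
  # before the first delayed sample: planning position
  expect_equal(delayed_view(ramp, latency_model(100, 0, 1), 0.05, 4),
               c(0, 0, 0))
})

test_that("latency draws are reproducible, clipped and parameterized", {
  lat <- latency_model(100, 15, seed = 4)
  expect_identical(latency_draws(lat, 50), latency_draws(lat, 50))
  expect_true(all(latency_draws(latency_model(1, 50, seed = 1), 200) >= 0))
  expect_error(latency_model(-1, 5), ">= 0")
})

test_that("offset and rotation grids enumerate the full Cartesian product", {
  expect_equal(nrow(offset_grid(3, 1)), 343)
  expect_equal(nrow(offset_grid(2, 1)), 125)
  g0 <- offset_grid(0, 1)
  expect_equal(nrow(g0), 1)
  expect_equal(as.numeric(g0), c(0, 0, 0))
  expect_error(offset_grid(3, 0), "step")
  expect_error(offset_grid(2.5, 1), "multiple")

  expect_equal(nrow(rotation_grid(seq(-20, 20, 1), 0)), 41)
  expect_equal(nrow(rotation_grid(seq(-20, 20, 4), seq(-20, 20, 4))), 121)
  expect_error(rotation_grid(numeric(0)), "empty")
})

test_that("displace_and_rotate composes pitch-then-roll about the pivot", {
  # identity
  expect_equal(displace_and_rotate(c(1, 2, 3), rotation_spec(0, 0)),
               rbind(c(1, 2, 3)))
  # quarter turn: anterior -> superior under +90 deg pitch
  expect_equal(as.numeric(displace_and_rotate(c(0, 10, 0),
                                              rotation_spec(90, 0))),
               c(0, 0, 10))
  # matrix-composition oracle: R_roll %*% R_pitch in the stated order
  rot <- rotation_spec(7, 11, pivot = c(1, -2, 3))
  cp <- cospi(7 / 180); sp <- sinpi(7 / 180)
  cr <- cospi(11 / 180); sr <- sinpi(11 / 180)
  Rp <- rbind(c(1, 0, 0), c(0, cp, -sp), c(0, sp, cp))
  Rr <- rbind(c(cr, -sr, 0), c(sr, cr, 0), c(0, 0, 1))
  p <- c(4, 5, 6)
  manual <- Rr %*% (Rp %*% (p - rot$pivot)) + rot$pivot + c(0.5, 0, -0.5)
  expect_equal(as.numeric(displace_and_rotate(p, rot, c(0.5, 0, -0.5))),
               as.numeric(manual), tolerance = 1e-12)
  # distances to the pivot preserved when shift = 0
  with_seed(5, {
    pts <- matrix(stats::rnorm(30, sd = 20), ncol = 3)
    rot <- rotation_spec(-13, 5, pivot = c(2, 2, 2))
    out <- displace_and_rotate(pts, rot)
    d0 <- sqrt(rowSums(sweep(pts, 2, rot$pivot)^2))
    d1 <- sqrt(rowSums(sweep(out, 2, rot$pivot)^2))
    expect_equal(d0, d1, tolerance = 1e-12)
  })
})
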