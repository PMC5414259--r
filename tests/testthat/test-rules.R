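# Unit behaviour of the individual interaction rules.

test_that("repulsion heading is the negated normalized displacement sum", {
  st <- make_state(rbind(c(0, 0), c(1, 0)), c(0, 0))
  expect_equal(repulsion_heading(1, st, zor_radius = 5), c(-1, 0))

  st <- make_state(rbind(c(0, 0), c(1, 0), c(0, 1)), c(0, 0, 0))
  expect_equal(repulsion_heading(1, st, 5), c(-sqrt(2) / 2, -sqrt(2) / 2))

  # symmetric neighbourhood: zero sum resolved by the current heading
  st <- make_state(rbind(c(0, 0), c(1, 0), c(-1, 0)), c(pi / 3, 0, 0))
  expect_equal(repulsion_heading(1, st, 5), c(cos(pi / 3), sin(pi / 3)))

  # no neighbour inside the zone -> absent
  st <- make_state(rbind(c(0, 0), c(10, 0)), c(0, 0))
  expect_null(repulsion_heading(1, st, 5))
})

test_that("alignment heading is the normalized velocity sum including self", {
  pos <- rbind(c(0, 0), c(1, 0), c(0, 1))
  st <- particle_state(pos, velocities = rbind(c(1, 0), c(1, 0), c(0, 1)))
  expect_equal(alignment_heading(1, st, zoa_radius = 5),
               c(2, 1) / sqrt(5))

  # isolated particle keeps its own heading
  st <- make_state(rbind(c(0, 0), c(100, 0)), c(pi / 4, 0))
  expect_equal(alignment_heading(1, st, 5), c(cos(pi / 4), sin(pi / 4)))

  # exactly cancelling velocities -> current heading retained
  st <- particle_state(rbind(c(0, 0), c(1, 0)),
                       velocities = rbind(c(1, 0), c(-1, 0)),
                       headings = c(0, pi))
  expect_equal(alignment_heading(1, st, 5), c(1, 0))
})

test_that("local order is 1 for aligned sets, 0 for cancelling sets", {
  st <- make_state(rbind(c(0, 0), c(1, 0), c(0, 1)), rep(0.7, 3))
  expect_equal(local_order(1, st, zoa_radius = 5), 1)

  st <- make_state(rbind(c(0, 0), c(1, 0)), c(0, pi))
  expect_equal(local_order(1, st, zoa_radius = 5), 0)

  st <- make_state(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)),
                   c(0, pi / 2, pi, 3 * pi / 2))
  expect_equal(local_order(1, st, zoa_radius = 5), 0)

  # isolated particle: psi = 1, so it moves at full speed
  st <- make_state(rbind(c(0, 0), c(500, 0)), c(1, 2))
  expect_equal(local_order(1, st, zoa_radius = 5), 1)
})

test_that("speed rule v = v0 psi^gamma", {
  expect_equal(update_speed(1, v0 = 5, gamma = 1), 5)
  expect_equal(update_speed(0, v0 = 5, gamma = 1), 0)
  expect_equal(update_speed(0.25, v0 = 2, gamma = 0.5), 1)
  expect_error(update_speed(1.2, 5, 1), "psi")
  expect_error(update_speed(-0.1, 5, 1), "psi")
})

test_that("noise rotation preserves the norm and has zero-mean angles", {
  h <- c(cos(0.3), sin(0.3))
  set.seed(1)
  expect_equal(noise_rotation(h, eta = 0), h)
  set.seed(2)
  out <- noise_rotation(h, eta = 2)
  expect_equal(sqrt(sum(out^2)), 1, tolerance = 1e-12)

  # Monte-Carlo moment check of the sampler
  set.seed(3)
  n <- 1e5
  angs <- vapply(seq_len(n), function(i) {
    r <- noise_rotation(c(1, 0), eta = 0.1)
    atan2(r[2], r[1])
  }, numeric(1))
  expect_lt(abs(mean(angs)), 3 * 0.1 / sqrt(n))
  expect_equal(sd(angs), 0.1, tolerance = 0.02)
})

test_that("wall rotation follows theta = v0 phi / d with damping and sign", {
  R <- 380
  # radially outward heading: phi = 0 -> no turn
  expect_equal(wall_rotation(c(100, 0), c(1, 0), v0 = 5, arena_radius = R), 0)

  # constructed phi = pi/4, d = 10 at unit speed: |theta| = pi/40,
  # rotating toward the inward normal (counterclockwise here)
  phi <- pi / 4
  h <- c(cos(phi), sin(phi))
  pos <- c(R, 0) - 10 * h
  th <- wall_rotation(pos, h, v0 = 1, arena_radius = R)
  expect_equal(abs(th), pi / 40, tolerance = 1e-12)
  expect_gt(th, 0)

  # near the centre the turn is bounded by v0 (pi/2) / d with d ~ R
  set.seed(4)
  worst <- max(vapply(1:200, function(i) {
    p <- runif(2, -1, 1)
    a <- runif(1, 0, 2 * pi)
    abs(wall_rotation(p, c(cos(a), sin(a)), v0 = 5, arena_radius = R))
  }, numeric(1)))
  expect_lte(worst, 5 * (pi / 2) / (R - 2))

  # origin is well-posed: impact distance R, phi = 0
  expect_equal(wall_rotation(c(0, 0), c(0, 1), 5, R), 0)
})
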