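# Whole-system stepping: priority of repulsion, containment, determinism,
# and agreement between the R reference step and the compiled run loop.

test_that("repulsion has absolute priority over alignment in a step", {
  # two particles inside each other's repulsion zone on the x-axis, no
  # noise, huge arena so the wall correction is negligible
  p <- spp_params(n_particles = 2, arena_radius = 1e6, zor_radius = 7.5,
                  zoa_radius_base = 75, eta = 0, n_steps = 2, seed = 1)
  st <- particle_state(rbind(c(-2, 0), c(2, 0)),
                       velocities = rbind(c(0, 1), c(0, 1)))
  out <- spp_step(st, p)
  expect_lt(ang_dist(out$headings[1], pi), 1e-4)  # points away along -x
  expect_lt(ang_dist(out$headings[2], 0), 1e-4)
  # the pre-noise desired heading equals the repulsion rule's output
  expect_equal(repulsion_heading(1, st, p$zor_radius), c(-1, 0))
  expect_equal(repulsion_heading(2, st, p$zor_radius), c(1, 0))
})

test_that("outside the repulsion zone the desired heading follows alignment", {
  p <- spp_params(n_particles = 2, arena_radius = 1e6, eta = 0,
                  n_steps = 2, seed = 1)
  st <- particle_state(rbind(c(-20, 0), c(20, 0)),
                       velocities = rbind(c(0, 2), c(2, 0)))
  out <- spp_step(st, p)
  expect_lt(ang_dist(out$headings[1], pi / 4), 1e-4)
  expect_lt(ang_dist(out$headings[2], pi / 4), 1e-4)
})

test_that("an isolated noiseless particle streams at v0", {
  p <- spp_params(n_particles = 1, eta = 0, n_steps = 50, burn_in = 0,
                  seed = 5)
  tr <- spp_run(p)
  sp <- sqrt(tr$vx^2 + tr$vy^2)
  expect_true(all(abs(sp - p$v0) < 1e-12))
  # displacement per step is v0 while far from the wall
  dx <- diff(tr$x[, 1]); dy <- diff(tr$y[, 1])
  expect_true(all(abs(sqrt(dx^2 + dy^2) - p$v0) < 1e-9))
})

test_that("R reference step and compiled step agree to machine precision", {
  for (seed in 1:3) {
    p <- spp_params(n_particles = 12, eta = 0, n_steps = 2, burn_in = 0,
                    seed = seed)
    set.seed(seed + 100)
    pos <- cbind(runif(12, -250, 250), runif(12, -250, 250))
    th <- runif(12, 0, 2 * pi)
    st <- particle_state(pos, headings = th, speeds = p$v0)
    set.seed(1); ref <- spp_step(st, p)
    set.seed(1)
    cpp <- pmfish:::cpp_spp_run(pos[, 1], pos[, 2],
                                p$v0 * cos(th), p$v0 * sin(th), th,
                                p$arena_radius, p$zor_radius, p$zoa_radius,
                                p$v0, p$gamma, p$eta, p$dt, 1L, 0L, TRUE)
    expect_equal(ref$positions, cbind(cpp$x[1, ], cpp$y[1, ]),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(ref$velocities, cbind(cpp$vx[1, ], cpp$vy[1, ]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("runs are contained, speed-bounded and deterministic", {
  p <- spp_params(n_particles = 20, n_steps = 3000, seed = 11)
  tr1 <- spp_run(p)
  tr2 <- spp_run(p)
  expect_identical(tr1$x, tr2$x)        # bit-identical trajectories
  expect_identical(tr1$vy, tr2$vy)
  expect_lte(max(sqrt(tr1$x^2 + tr1$y^2)), p$arena_radius)
  expect_lte(max(sqrt(tr1$vx^2 + tr1$vy^2)), p$v0 * (1 + 1e-12))
  # headings are consistent with velocity direction wherever speed > 0
  sp <- sqrt(tr1$vx^2 + tr1$vy^2)
  moving <- sp > 1e-8
  dh <- atan2(tr1$vy[moving], tr1$vx[moving]) - tr1$heading[moving]
  expect_lt(max(abs(sin(dh / 2))), 1e-9)  # equal angles modulo 2 pi
})

test_that("clamp containment also keeps particles inside", {
  p <- spp_params(n_particles = 10, n_steps = 1500, seed = 3,
                  containment_mode = "clamp", v0 = 10)
  tr <- spp_run(p)
  expect_lte(max(sqrt(tr$x^2 + tr$y^2)), p$arena_radius * (1 + 1e-12))
})

test_that("run bookkeeping: retained frames and burn-in", {
  p <- spp_params(n_particles = 3, n_steps = 10, burn_in = 9, seed = 2)
  tr <- spp_run(p)
  expect_equal(n_frames(tr), 1L)
  expect_equal(tr$frame_index, 10L)
  p2 <- spp_params(n_particles = 3, n_steps = 10, burn_in = 4, seed = 2)
  expect_equal(n_frames(spp_run(p2)), 6L)
})
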