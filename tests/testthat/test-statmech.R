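# Group geometry, polar order, pair distribution, Boltzmann inversion,
# mean force, and profile features.

test_that("convex-hull area matches closed-form polygons", {
  expect_equal(group_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 1)
  # regular pentagon, unit circumradius: area (5/2) sin(2 pi / 5)
  a <- 2 * pi * (0:4) / 5
  expect_equal(group_area(cbind(cos(a), sin(a))), (5 / 2) * sin(2 * pi / 5),
               tolerance = 1e-12)
  # interior points do not change the hull
  expect_equal(group_area(rbind(cbind(cos(a), sin(a)), c(0.1, 0))),
               (5 / 2) * sin(2 * pi / 5))
  expect_error(group_area(rbind(c(0, 0), c(1, 1), c(2, 2))), "collinear|degenerate")
  expect_error(group_area(rbind(c(0, 0), c(1, 1))), "3 points")
})

test_that("density and packing fraction are simple ratios with guards", {
  expect_equal(number_density(60, 600), 0.1)
  expect_equal(number_density(0, 10), 0)
  expect_equal(number_density(10, 4000), 0.0025)
  expect_error(number_density(5, 0), "positive")

  expect_equal(packing_fraction(rep(1, 10), 1000), 0.01)
  expect_warning(pf <- packing_fraction(2, 120, n = 60), "exceeds 1")
  expect_equal(pf, 1)  # saturation boundary, flagged
  # default elliptical body model: 0.05 pi L^2
  expect_equal(body_area_ellipse(10), 0.05 * pi * 100)
})

test_that("polar order is exact on alignment and cancellation cases", {
  expect_equal(polar_order(c(0.3, 0.3, 0.3, 0.3)), 1, tolerance = 1e-12)
  expect_equal(polar_order(c(0, pi)), 0, tolerance = 1e-12)
  expect_equal(polar_order(c(0, pi / 2, pi, 3 * pi / 2)), 0, tolerance = 1e-12)
  # two frames of internally identical headings (rows are frames)
  expect_equal(polar_order(matrix(c(0, pi / 2, 0, pi / 2), 2, 2)), 1)
  tr <- aligned_group(7, 4, heading = 1.2, seed = 3)
  expect_equal(polar_order(tr), 1, tolerance = 1e-12)
})

test_that("pair counts sum to N(N-1) per frame before normalization", {
  tr <- uniform_disc(15, 7, arena_radius = 100, seed = 2)
  g <- pair_distribution(tr, analysis_params(bin_width = 5, arena_radius = 100))
  expect_equal(sum(g$count), 7 * 15 * 14)
})

test_that("a fixed-separation pair yields single-bin support", {
  tr <- fixed_pair(50, n_frames = 200, arena_radius = 380, seed = 8)
  g <- pair_distribution(tr, analysis_params(bin_width = 10, arena_radius = 380))
  nz <- which(g$value > 0)
  expect_length(nz, 1)
  expect_equal(g$r[nz], 45)  # bin (40, 50] has center 45
  expect_equal(sum(g$count), 200 * 2)
})

test_that("edge-corrected g is flat at 1 for a uniform ensemble", {
  tr <- uniform_disc(100, 200, arena_radius = 380, seed = 5)
  g <- pair_distribution(tr, analysis_params(bin_width = 20, arena_radius = 380))
  ok <- g$count >= 200
  expect_gt(sum(ok), 20)
  se <- g$value / sqrt(g$count / 2)
  expect_lt(max(abs(g$value[ok] - 1) / se[ok]), 4)
  expect_equal(mean(g$value[ok]), 1, tolerance = 0.01)
})

test_that("shell-normalized g follows the analytic boundary depletion", {
  tr <- uniform_disc(100, 200, arena_radius = 380, seed = 5)
  ap <- analysis_params(bin_width = 20, arena_radius = 380,
                        normalization_mode = "shell")
  g <- pair_distribution(tr, ap)
  # independent oracle: uniform-disc pair-distance density over annulus mass
  R <- 380
  f <- function(r) (4 * r / (pi * R^2)) * acos(pmin(r / (2 * R), 1)) -
    (2 * r^2 / (pi * R^3)) * sqrt(pmax(1 - r^2 / (4 * R^2), 0))
  expected <- vapply(seq_along(g$r), function(b) {
    integrate(f, g$r[b] - 10, g$r[b] + 10)$value /
      (2 * pi * g$r[b] * 20 / (pi * R^2))
  }, numeric(1))
  ok <- g$count >= 200
  expect_lt(max(abs(g$value[ok] - expected[ok])), 0.05)
  # depletion: well below 1 at large r
  expect_lt(g$value[which.min(abs(g$r - 600))], 0.5)
})

test_that("smoothing is a shrinking-window centred moving average", {
  prof <- radial_profile(1:10, rep(2, 10), rep(1, 10), kind = "g")
  expect_equal(smooth_profile(prof, 5)$value, rep(2, 10))

  imp <- radial_profile(1:11, c(rep(0, 5), 1, rep(0, 5)), kind = "g")
  sm <- smooth_profile(imp, 5)
  expect_equal(sm$value[4:8], rep(0.2, 5))
  expect_equal(sum(sm$value[4:8]), 1)

  expect_equal(smooth_profile(imp, 1)$value, imp$value)  # identity
  expect_error(smooth_profile(imp, 4), "odd")
  # counts propagate by summation
  cnt <- radial_profile(1:10, rep(1, 10), rep(2, 10), kind = "g")
  expect_equal(smooth_profile(cnt, 5)$count[5], 10)
})

test_that("Boltzmann inversion maps g to -kBT log g with NA gaps", {
  g <- radial_profile(1:4, c(1, exp(-1), exp(-2), 0), kind = "g")
  U <- boltzmann_invert(g)
  expect_equal(U$value[1:3], c(0, 1, 2))
  expect_true(is.na(U$value[4]))
  U2 <- boltzmann_invert(g, kBT = 2)
  expect_equal(U2$value[2], 2)
  expect_error(boltzmann_invert(radial_profile(1:3, c(0, 0, 0), kind = "g")),
               "zero")
})

test_that("mean force differentiates U per segment, exactly for quadratics", {
  h <- 2
  r <- seq(2, 40, by = h)
  U <- radial_profile(r, r^2 / 2, kind = "U")
  Fp <- mean_force(U)
  inner <- 2:(length(r) - 1)
  expect_equal(Fp$value[inner], -r[inner], tolerance = 1e-10)

  Uc <- radial_profile(r, rep(3, length(r)), kind = "U")
  expect_equal(mean_force(Uc)$value, rep(0, length(r)))

  Ul <- radial_profile(r, r, kind = "U")
  expect_equal(mean_force(Ul)$value, rep(-1, length(r)))

  # a gap splits the profile; no differencing across it
  vals <- r^2 / 2
  vals[8] <- NA
  Ug <- radial_profile(r, vals, kind = "U")
  Fg <- mean_force(Ug)
  expect_true(is.na(Fg$value[8]))
  expect_equal(Fg$value[9], -(vals[10] - vals[9]) / h)  # one-sided restart
  expect_error(mean_force(radial_profile(1:5, c(1, NA, 2, NA, 3), kind = "U")),
               "3 consecutive")
})

test_that("profile features find the peak and half-radial width", {
  r <- 0:200
  v <- ifelse(r <= 30, 1 + 24 * r / 30, pmax(25 - 24 * (r - 30) / 115, 0.2))
  g <- radial_profile(r, v, kind = "g")
  ft <- profile_features(g)
  expect_equal(ft$peak_radius, 30)
  expect_equal(ft$peak_value, 25)
  expect_equal(ft$half_radial_width, 145)

  # equal maxima: the smallest radius wins
  v2 <- rep(1, 61); v2[c(21, 41)] <- 5
  ft2 <- profile_features(radial_profile(0:60, v2, kind = "g"))
  expect_equal(ft2$peak_radius, 20)

  expect_error(profile_features(radial_profile(1:10, rep(1, 10), kind = "g")),
               "flat")
  # peak never above baseline: width undefined
  v3 <- c(0.2, 0.5, 0.9, 0.5, 0.2)
  ft3 <- profile_features(radial_profile(1:5, v3, kind = "g"))
  expect_true(is.na(ft3$half_radial_width))
})

test_that("angular occupancy bins individuals by arena segment and time", {
  # one stationary particle at polar angle 10 degrees
  tr <- new_trajectory(matrix(cos(10 * pi / 180) * 50, 6, 1),
                       matrix(sin(10 * pi / 180) * 50, 6, 1),
                       params = list(arena_radius = 380))
  occ <- angular_occupancy(tr, segment_degrees = 20, frames_per_bin = 2)
  expect_equal(dim(occ), c(18L, 3L))
  expect_equal(unname(occ[1, ]), rep(2L, 3))
  expect_equal(sum(occ), 6)

  # column sums equal N * frames_per_bin for complete observations
  tr2 <- uniform_disc(12, 10, seed = 6)
  occ2 <- angular_occupancy(tr2, 20, frames_per_bin = 5)
  expect_equal(unname(colSums(occ2)), rep(60, 2))

  # many uniform angles: rows are near-uniform (multinomial check)
  tr3 <- uniform_disc(50, 200, seed = 7)
  occ3 <- angular_occupancy(tr3, 20, frames_per_bin = 200)
  n_tot <- sum(occ3)
  expected <- n_tot / 18
  z <- (occ3[, 1] - expected) / sqrt(expected)
  expect_lt(max(abs(z)), 4)

  expect_error(angular_occupancy(tr3, 25), "divide")
})

test_that("group_stats ties the scalar observables together", {
  tr <- uniform_disc(30, 5, arena_radius = 100, seed = 9)
  tr$heading <- matrix(0.5, 5, 30)
  st <- group_stats(tr, body_length = 7.5)
  expect_gt(st$area, 0)
  expect_equal(st$density, 30 / st$area)
  expect_equal(st$packing_fraction, 30 * body_area_ellipse(7.5) / st$area)
  expect_equal(st$polar_order, 1)
})
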