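# Synthetic ensembles with known statistical structure: exact oracles for
# the analysis chain (uniform ideal gas for g = 1, delta-separation pairs,
# Boltzmann-weighted pairs at a known potential, perfectly aligned groups).

runif_disc <- function(n, R) {
  rad <- R * sqrt(runif(n))
  ang <- 2 * pi * runif(n)
  cbind(rad * cos(ang), rad * sin(ang))
}

#' Uniform (ideal-gas) ensemble in the arena disc
#'
#' Positions independent and uniform over the disc in every frame; the
#' exact null model for the pair distribution function (edge-corrected
#' g identically 1).
#'
#' @param n_particles particles per frame.
#' @param n_frames number of frames.
#' @param arena_radius disc radius.
#' @param seed RNG seed.
#' @return a trajectory (positions only).
#' @export
uniform_disc <- function(n_particles, n_frames, arena_radius = 380, seed = 1L) {
  set.seed(seed)
  p <- runif_disc(n_particles * n_frames, arena_radius)
  new_trajectory(matrix(p[, 1], n_frames, n_particles),
                 matrix(p[, 2], n_frames, n_particles),
                 params = list(arena_radius = arena_radius,
                               n_particles = n_particles, kind = "uniform_disc"),
                 seed = as.integer(seed))
}

#' Rigid pair at fixed separation
#'
#' Two particles at an exact separation, rigidly placed at a random position
#' and orientation inside the arena in every frame (midpoint uniform in the
#' concentric disc that keeps both ends inside). The resulting pair
#' distribution has support in a single bin.
#'
#' @param separation pair distance (must fit in the arena).
#' @inheritParams uniform_disc
#' @return a trajectory with 2 individuals.
#' @export
fixed_pair <- function(separation, n_frames, arena_radius = 380, seed = 1L) {
  if (separation <= 0 || separation >= 2 * arena_radius)
    stop("separation must be positive and smaller than the arena diameter")
  set.seed(seed)
  c0 <- runif_disc(n_frames, arena_radius - separation / 2)
  ang <- 2 * pi * runif(n_frames)
  dx <- separation / 2 * cos(ang)
  dy <- separation / 2 * sin(ang)
  new_trajectory(cbind(c0[, 1] - dx, c0[, 1] + dx),
                 cbind(c0[, 2] - dy, c0[, 2] + dy),
                 params = list(arena_radius = arena_radius, n_particles = 2L,
                               kind = "fixed_pair", separation = separation),
                 seed = as.integer(seed))
}

#' Perfectly aligned group
#'
#' Uniform random positions with every velocity along a common heading; the
#' polar order parameter of such an ensemble is exactly 1.
#'
#' @param heading common heading angle in radians.
#' @param speed common speed (default 1).
#' @inheritParams uniform_disc
#' @return a trajectory with velocities and headings.
#' @export
aligned_group <- function(n_particles, n_frames, heading = 0, speed = 1,
                          arena_radius = 380, seed = 1L) {
  set.seed(seed)
  p <- runif_disc(n_particles * n_frames, arena_radius)
  ones <- matrix(1, n_frames, n_particles)
  new_trajectory(matrix(p[, 1], n_frames, n_particles),
                 matrix(p[, 2], n_frames, n_particles),
                 vx = speed * cos(heading) * ones,
                 vy = speed * sin(heading) * ones,
                 heading = heading * ones,
                 params = list(arena_radius = arena_radius,
                               n_particles = n_particles, kind = "aligned_group"),
                 seed = as.integer(seed))
}

#' Truncated harmonic well potential
#'
#' U(r) = depth * min(((r - r0) / width)^2, 1): a harmonic well of the given
#' depth centred at r0, truncated to a flat plateau beyond one width. A
#' convenient known potential for validating the Boltzmann inversion.
#'
#' @param r0 well centre.
#' @param width half-width at which the well reaches the plateau.
#' @param depth well depth in kBT units.
#' @return vectorized function of r.
#' @export
harmonic_well <- function(r0 = 80, width = 60, depth = 4) {
  stopifnot(r0 > 0, width > 0, depth > 0)
  function(r) depth * pmin(((r - r0) / width)^2, 1)
}

# Integrated autocorrelation time by Geyer's initial positive sequence:
# tau = 1 + 2 sum rho_k, truncated at the first non-positive sum of
# adjacent autocorrelation pairs.
integrated_autocorr_time <- function(x, lag_max = min(length(x) - 2L, 2000L)) {
  if (stats::sd(x) == 0) return(1)
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[-1]
  tau <- 1
  k <- 1L
  while (2L * k <= length(rho)) {
    s <- rho[2L * k - 1L] + rho[2L * k]
    if (!is.finite(s) || s <= 0) break
    tau <- tau + 2 * s
    k <- k + 1L
  }
  max(tau, 1)
}

#' Boltzmann-weighted pair ensemble by Metropolis sampling
#'
#' Sample two-particle configurations in the arena disc from the stationary
#' density proportional to exp(-U(|r1 - r2|) / kBT), each particle otherwise
#' uniform, by a Metropolis chain with uniform single-particle displacement
#' moves. The step size is tuned automatically to a 30--50% acceptance
#' band, the chain is thinned by five times the integrated autocorrelation
#' time of the pair distance (estimated from a pilot run by the
#' initial-sequence method) so retained frames are approximately
#' independent, and everything is reproducible from the seed.
#'
#' @param potential pair potential: a vectorized function of r, or a
#'   data.frame with columns `r` and `U` tabulating it on (0, 2R\];
#'   non-finite values mark distances whose moves are rejected.
#' @param n_frames retained (thinned) configurations.
#' @param arena_radius disc radius.
#' @param kBT energy scale of the target density (default 1).
#' @param seed RNG seed.
#' @param verbose log acceptance rate, step size and thinning to stderr
#'   (default TRUE).
#' @return a trajectory with 2 individuals; attributes `acceptance_rate`,
#'   `step_size`, `thin` and `tau` record the chain diagnostics.
#' @export
metropolis_pair <- function(potential, n_frames, arena_radius = 380,
                            kBT = 1, seed = 1L, verbose = TRUE) {
  stopifnot(n_frames >= 1, arena_radius > 0, kBT > 0)
  set.seed(seed)
  R <- arena_radius
  m <- 4096L
  rtab <- seq(0, 2 * R, length.out = m)
  if (is.function(potential)) {
    Utab <- potential(rtab)
  } else {
    stopifnot(is.data.frame(potential), all(c("r", "U") %in% names(potential)))
    Utab <- stats::approx(potential$r, potential$U, xout = rtab, rule = 2)$y
  }
  if (length(Utab) != m || all(!is.finite(Utab)))
    stop("potential must be finite somewhere on (0, 2R]")

  state <- as.vector(t(runif_disc(2, R)))

  # tune the step size to a 30--50% acceptance band
  step <- R / 4
  for (round in 1:30) {
    res <- cpp_pair_chain(state, R, Utab, 2 * R, kBT, step, 200L, 0L)
    state <- res$state
    acc <- res$accepted / 200
    if (acc < 0.3) step <- step * 0.7
    else if (acc > 0.5) step <- step * 1.4
    else break
    step <- min(step, 2 * R)
  }

  # burn-in, then a pilot run to estimate the distance autocorrelation time
  res <- cpp_pair_chain(state, R, Utab, 2 * R, kBT, step, 2000L, 0L)
  state <- res$state
  pilot_n <- 5000L
  res <- cpp_pair_chain(state, R, Utab, 2 * R, kBT, step, pilot_n, 1L)
  state <- res$state
  s <- res$samples
  dpil <- sqrt((s[, 1] - s[, 3])^2 + (s[, 2] - s[, 4])^2)
  tau <- integrated_autocorr_time(dpil)
  thin <- max(1L, as.integer(ceiling(5 * tau)))

  n_iter <- thin * n_frames
  res <- cpp_pair_chain(state, R, Utab, 2 * R, kBT, step, n_iter, thin)
  s <- res$samples
  acc_rate <- res$accepted / n_iter
  if (verbose)
    message(sprintf(
      "metropolis_pair: acceptance %.1f%%, step %.2f, tau %.1f, thin %d",
      100 * acc_rate, step, tau, thin))
  traj <- new_trajectory(cbind(s[, 1], s[, 3]), cbind(s[, 2], s[, 4]),
                         params = list(arena_radius = R, n_particles = 2L,
                                       kind = "metropolis_pair", kBT = kBT),
                         seed = as.integer(seed))
  attr(traj, "acceptance_rate") <- acc_rate
  attr(traj, "step_size") <- step
  attr(traj, "thin") <- thin
  attr(traj, "tau") <- tau
  traj
}
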