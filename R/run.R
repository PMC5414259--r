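#' Run the self-propelled particle model
#'
#' Initialize particle positions uniformly over the arena disc and headings
#' uniformly over \[0, 2 pi) (all particles start at speed v0), iterate the
#' synchronous update for `n_steps` steps, and keep the frames after
#' `burn_in` as the steady-state sample. The whole run is reproducible from
#' `params$seed`; the iteration itself runs in compiled code and is
#' bit-identical to repeated [spp_step()] calls under the same RNG stream.
#'
#' @param params an [spp_params()].
#' @param init optional [particle_state()] used instead of the random
#'   initial condition (the seed then only drives the noise).
#' @return a trajectory (frames `burn_in + 1 ... n_steps`) carrying the
#'   parameters and seed.
#' @export
#' @examples
#' tr <- spp_run(spp_params(n_particles = 5, n_steps = 200, seed = 42))
#' tr
spp_run <- function(params, init = NULL) {
  stopifnot(inherits(params, "spp_params"))
  set.seed(params$seed)
  n <- params$n_particles
  if (is.null(init)) {
    rad <- params$arena_radius * sqrt(runif(n))
    ang <- 2 * pi * runif(n)
    th <- 2 * pi * runif(n)
    x0 <- rad * cos(ang); y0 <- rad * sin(ang)
    vx0 <- params$v0 * cos(th); vy0 <- params$v0 * sin(th)
  } else {
    stopifnot(inherits(init, "particle_state"),
              nrow(init$positions) == n)
    x0 <- init$positions[, 1]; y0 <- init$positions[, 2]
    vx0 <- init$velocities[, 1]; vy0 <- init$velocities[, 2]
    th <- init$headings
  }
  res <- cpp_spp_run(x0, y0, vx0, vy0, th,
                     params$arena_radius, params$zor_radius,
                     params$zoa_radius, params$v0, params$gamma,
                     params$eta, params$dt,
                     params$n_steps, params$burn_in,
                     params$containment_mode == "reflect")
  new_trajectory(res$x, res$y, res$vx, res$vy, res$heading,
                 params = unclass(params), seed = params$seed,
                 frame_index = seq.int(params$burn_in + 1L, params$n_steps))
}
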