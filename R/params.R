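#' Simulation parameters
#'
#' Bundle and validate all constants of the self-propelled particle model.
#' Lengths are in model units (1 unit corresponds to 1 mm of arena); time is
#' in integration steps.
#'
#' @param n_particles number of particles N.
#' @param arena_radius radius of the circular arena (default 380).
#' @param zor_radius radius of the zone of repulsion. Default 7.5, one body
#'   length of the smallest size class; a calibration parameter.
#' @param zoa_radius_base radius of the zone of alignment for the reference
#'   (smallest) size class. Default 75, ten small-fish body lengths; a
#'   calibration parameter.
#' @param k dimensionless body-size scale factor; the effective alignment
#'   zone is `k * zoa_radius_base`. The three size classes correspond to
#'   k = 1, 1.73 and 3.07.
#' @param v0 maximal particle speed per step. The default 5 corresponds to
#'   an average experimental speed of 100 mm/s converted with a behavioural
#'   reaction time of 0.05 s (see [calibrate_v0()]).
#' @param gamma exponent of the speed rule v = v0 * psi^gamma (default 1).
#' @param eta standard deviation of the Gaussian heading noise, radians
#'   (default 0.1).
#' @param dt integration time step (default 1).
#' @param n_steps total number of update steps.
#' @param burn_in number of initial steps discarded before statistics are
#'   collected; defaults to half of `n_steps`.
#' @param seed integer seed for the run.
#' @param containment_mode `"reflect"` (specular reflection at the wall,
#'   default) or `"clamp"` (radial projection back onto the boundary).
#'
#' @return An object of class `spp_params` (a validated list).
#' @seealso [spp_run()], [calibrate_v0()], [body_size_scale()]
#' @export
#' @examples
#' p <- spp_params(n_particles = 10, n_steps = 100, seed = 1)
#' p$zoa_radius   # k * zoa_radius_base
spp_params <- function(n_particles = 30,
                       arena_radius = 380,
                       zor_radius = 7.5,
                       zoa_radius_base = 75,
                       k = 1,
                       v0 = 5,
                       gamma = 1,
                       eta = 0.1,
                       dt = 1,
                       n_steps = 20000L,
                       burn_in = NULL,
                       seed = 1L,
                       containment_mode = c("reflect", "clamp")) {
  containment_mode <- match.arg(containment_mode)
  n_steps <- as.integer(n_steps)
  if (is.null(burn_in)) burn_in <- n_steps %/% 2L
  burn_in <- as.integer(burn_in)

  stopifnot(
    n_particles >= 1,
    arena_radius > 0, zor_radius > 0, zoa_radius_base > 0, k > 0,
    v0 > 0, dt > 0,
    gamma >= 0, eta >= 0,
    n_steps >= 1, burn_in >= 0
  )
  if (zor_radius >= k * zoa_radius_base)
    stop("zor_radius must be smaller than the scaled alignment radius k * zoa_radius_base")
  if (burn_in >= n_steps)
    stop("burn_in must be smaller than n_steps")

  p <- list(
    n_particles = as.integer(n_particles),
    arena_radius = arena_radius,
    zor_radius = zor_radius,
    zoa_radius_base = zoa_radius_base,
    k = k,
    zoa_radius = k * zoa_radius_base,
    v0 = v0,
    gamma = gamma,
    eta = eta,
    dt = dt,
    n_steps = n_steps,
    burn_in = burn_in,
    seed = as.integer(seed),
    containment_mode = containment_mode
  )
  class(p) <- "spp_params"
  p
}

#' @export
print.spp_params <- function(x, ...) {
  cat("Self-propelled particle model parameters\n")
  cat(sprintf("  N = %d particles, arena radius %g\n", x$n_particles, x$arena_radius))
  cat(sprintf("  zor = %g, zoa = %g (base %g x k = %g)\n",
              x$zor_radius, x$zoa_radius, x$zoa_radius_base, x$k))
  cat(sprintf("  v0 = %g, gamma = %g, eta = %g, dt = %g\n",
              x$v0, x$gamma, x$eta, x$dt))
  cat(sprintf("  %d steps (%d burn-in), seed %d, containment '%s'\n",
              x$n_steps, x$burn_in, x$seed, x$containment_mode))
  invisible(x)
}

#' Analysis parameters
#'
#' Settings for the radial statistics: histogram bin width, maximal pair
#' separation, smoothing window for g(r), the energy scale kBT of the
#' Boltzmann inversion, and the normalization mode of the pair distribution
#' function.
#'
#' @param bin_width radial bin width (model units, default 1).
#' @param r_max largest pair separation binned; must not exceed the arena
#'   diameter. Defaults to the arena diameter.
#' @param smoothing_window odd width of the centred moving average applied to
#'   g(r) before inversion (default 5).
#' @param kBT energy scale of the inversion; the inverse temperature beta =
#'   1/kBT is a bookkeeping constant here, not a thermodynamic temperature
#'   (default 1).
#' @param normalization_mode `"edge_corrected"` (default) normalizes each bin
#'   by the exact expected ideal-gas pair count for uniform points in the
#'   arena disc, so a uniform ensemble gives g = 1 at every r;
#'   `"shell"` is the literal annulus-area normalization, which decays below
#'   1 at large r in a bounded arena.
#' @param arena_radius arena radius used by the edge correction.
#'
#' @return An object of class `analysis_params`.
#' @export
analysis_params <- function(bin_width = 1,
                            r_max = NULL,
                            smoothing_window = 5L,
                            kBT = 1,
                            normalization_mode = c("edge_corrected", "shell"),
                            arena_radius = 380) {
  normalization_mode <- match.arg(normalization_mode)
  if (is.null(r_max)) r_max <- 2 * arena_radius
  smoothing_window <- as.integer(smoothing_window)
  stopifnot(bin_width > 0, kBT > 0, arena_radius > 0,
            smoothing_window >= 1, r_max > 0)
  if (smoothing_window %% 2L == 0L)
    stop("smoothing_window must be odd")
  if (r_max > 2 * arena_radius + 1e-9)
    stop("r_max cannot exceed the arena diameter")
  structure(
    list(bin_width = bin_width, r_max = r_max,
         smoothing_window = smoothing_window, kBT = kBT,
         normalization_mode = normalization_mode,
         arena_radius = arena_radius),
    class = "analysis_params"
  )
}

#' Convert experimental speed to model speed
#'
#' The model's unit of time is set by the behavioural reaction time b, so the
#' maximal model speed is `v0 = b * v_exp` where `v_exp` is the average speed
#' measured in length units per second (b = 0.05 s in the parametrization
#' used here).
#'
#' @param b behavioural reaction time in seconds.
#' @param v_exp average experimental speed, length units per second.
#' @return model speed in length units per step.
#' @export
#' @examples
#' calibrate_v0(0.05, 100)  # 5 model units per step
calibrate_v0 <- function(b, v_exp) {
  if (!is.numeric(b) || b <= 0) stop("b must be a positive reaction time")
  if (!is.numeric(v_exp) || v_exp <= 0) stop("v_exp must be a positive speed")
  b * v_exp
}

#' Body-size scale factor for the alignment zone
#'
#' Fish of different size classes are modelled by scaling the alignment zone
#' with the ratio of body lengths to the reference (smallest) class, rounded
#' to the quoted precision: body lengths 7.5, 13 and 23 mm give k = 1, 1.73
#' and 3.07.
#'
#' @param body_length body length of the size class (mm).
#' @param reference_length body length of the reference class (default 7.5).
#' @param digits rounding of the reported factor (default 2).
#' @return dimensionless scale factor k.
#' @export
#' @examples
#' body_size_scale(13)  # 1.73
#' body_size_scale(23)  # 3.07
body_size_scale <- function(body_length, reference_length = 7.5, digits = 2) {
  stopifnot(body_length > 0, reference_length > 0)
  round(body_length / reference_length, digits)
}

#' Body area of an individual
#'
#' Default body model used by the packing fraction: an ellipse of length L
#' and width 0.2 L, i.e. area pi * (L/2) * (0.1 L) = 0.05 * pi * L^2.
#'
#' @param body_length body length L.
#' @param width_fraction body width as a fraction of length (default 0.2).
#' @return body area per individual.
#' @export
body_area_ellipse <- function(body_length, width_fraction = 0.2) {
  stopifnot(body_length > 0, width_fraction > 0)
  pi * (body_length / 2) * (width_fraction * body_length / 2)
}
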