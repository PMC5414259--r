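# Behavioural rules of the self-propelled particle model, exposed one by one
# so each can be tested against closed-form cases. spp_step() composes them;
# the compiled run loop mirrors them exactly.

unit_vec <- function(v) {
  m <- sqrt(sum(v^2))
  if (m == 0) return(NULL)
  v / m
}

heading_vec <- function(theta) c(cos(theta), sin(theta))

#' Repulsion (collision-avoidance) heading
#'
#' The repulsion rule has absolute priority: when any neighbour lies strictly
#' inside the zone of repulsion, the desired heading is the negated,
#' normalized sum of the displacement vectors to those neighbours,
#' u = -sum(r_j - r_i) / |sum(r_j - r_i)|.
#'
#' @param i focal particle index.
#' @param state a [particle_state()].
#' @param zor_radius radius of the zone of repulsion.
#' @return unit 2-vector, or `NULL` when no neighbour is inside the zone.
#'   In the degenerate case of a perfectly symmetric neighbourhood (zero
#'   vector sum) the particle's current heading is returned.
#' @export
repulsion_heading <- function(i, state, zor_radius) {
  pos <- state$positions
  d <- sqrt(rowSums((pos - matrix(pos[i, ], nrow(pos), 2, byrow = TRUE))^2))
  nbr <- which(d > 0 & d < zor_radius)
  nbr <- setdiff(nbr, i)
  # coincident particles (d == 0, j != i) are inside the zone too
  coin <- setdiff(which(d == 0), i)
  nbr <- union(nbr, coin)
  if (length(nbr) == 0L) return(NULL)
  s <- colSums(pos[nbr, , drop = FALSE]) - length(nbr) * pos[i, ]
  u <- unit_vec(-s)
  if (is.null(u)) heading_vec(state$headings[i]) else u
}

#' Alignment heading
#'
#' Vicsek-type alignment: the desired heading is the normalized sum of the
#' velocities of all particles within the zone of alignment, the focal
#' particle included. An isolated particle keeps its own heading; so does a
#' particle whose neighbourhood velocity sum vanishes exactly.
#'
#' @inheritParams repulsion_heading
#' @param zoa_radius radius of the zone of alignment.
#' @return unit 2-vector.
#' @export
alignment_heading <- function(i, state, zoa_radius) {
  pos <- state$positions
  d <- sqrt(rowSums((pos - matrix(pos[i, ], nrow(pos), 2, byrow = TRUE))^2))
  nbr <- which(d <= zoa_radius)      # includes i (d = 0)
  s <- colSums(state$velocities[nbr, , drop = FALSE])
  u <- unit_vec(s)
  if (is.null(u)) heading_vec(state$headings[i]) else u
}

#' Local polar order around a particle
#'
#' Magnitude of the mean heading unit vector over all particles inside the
#' behavioural zones of particle i (the repulsion zone is contained in the
#' alignment zone, so the union is the alignment disc), the focal particle
#' included. psi = 1 for perfect local alignment (in particular for an
#' isolated particle, which therefore moves at full speed), psi = 0 for
#' complete cancellation. Zero-speed particles contribute their stored
#' heading.
#'
#' @inheritParams alignment_heading
#' @param zor_radius repulsion-zone radius (kept in the signature for
#'   symmetry with the zonal rules; the union of the two zones is the
#'   alignment disc).
#' @return psi in \[0, 1\].
#' @export
local_order <- function(i, state, zor_radius = NULL, zoa_radius) {
  pos <- state$positions
  d <- sqrt(rowSums((pos - matrix(pos[i, ], nrow(pos), 2, byrow = TRUE))^2))
  nbr <- which(d <= zoa_radius)
  th <- state$headings[nbr]
  sqrt(mean(cos(th))^2 + mean(sin(th))^2)
}

#' Order-dependent speed
#'
#' v = v0 * psi^gamma: particles in a locally ordered neighbourhood move at
#' full speed, particles in a disordered one slow down; gamma sets the
#' sharpness of the transition.
#'
#' @param psi local polar order in \[0, 1\].
#' @param v0 maximal speed.
#' @param gamma speed exponent (gamma >= 0).
#' @return speed in \[0, v0\].
#' @export
update_speed <- function(psi, v0, gamma) {
  if (any(psi < 0 | psi > 1)) stop("psi must lie in [0, 1]")
  stopifnot(v0 > 0, gamma >= 0)
  v0 * psi^gamma
}

#' Gaussian heading noise
#'
#' Rotate a unit heading by an angle drawn from N(0, eta^2). The norm is
#' preserved exactly (the rotation is applied to the angle, not the
#' components).
#'
#' @param heading unit 2-vector.
#' @param eta noise standard deviation in radians.
#' @return rotated unit 2-vector.
#' @export
noise_rotation <- function(heading, eta) {
  stopifnot(eta >= 0)
  ang <- atan2(heading[2], heading[1]) + rnorm(1L, 0, 1) * eta
  heading_vec(ang)
}

#' Wall-avoidance turning angle
#'
#' A particle heading for the wall turns with rate theta = v0 * phi / d,
#' where d is the distance to the forward impact point of its heading ray on
#' the arena circle and phi is the unsigned angle between the heading and the
#' boundary normal at that point (phi in \[0, pi/2\) for a forward impact, so
#' a head-on approach has phi = 0 and produces no turn -- containment handles
#' that case). The turn is damped far from the wall (large d) and for
#' shallow approach angles, and its sign rotates the heading toward the
#' inward normal, away from the wall. The magnitude is capped at pi/2 per
#' step for numerical stability as d -> 0.
#'
#' @param position planar position strictly inside the arena.
#' @param heading unit 2-vector.
#' @param v0 maximal speed (sets the turning-rate scale).
#' @param arena_radius arena radius.
#' @return signed turning angle in radians, |theta| <= pi/2.
#' @export
wall_rotation <- function(position, heading, v0, arena_radius) {
  h <- unit_vec(heading)
  if (is.null(h)) stop("heading must be nonzero")
  b <- sum(position * h)
  disc <- b^2 + arena_radius^2 - sum(position^2)
  d <- -b + sqrt(max(disc, 0))
  impact <- position + d * h
  n_out <- impact / arena_radius
  cphi <- max(-1, min(1, sum(h * n_out)))
  phi <- acos(cphi)
  theta <- if (d > 1e-12) v0 * phi / d else pi / 2
  theta <- min(theta, pi / 2)
  cr <- -(h[1] * n_out[2] - h[2] * n_out[1])  # cross(heading, inward normal)
  if (cr >= 0) theta else -theta
}
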