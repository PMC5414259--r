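# One synchronous update of the whole system, in plain R. This is the
# readable reference implementation; spp_run() drives the compiled
# equivalent, and the two are cross-checked in the test-suite.

contain_reflect <- function(p_old, p_new, v, arena_radius) {
  q2 <- sum(p_new^2)
  R2 <- arena_radius^2
  if (q2 <= R2) return(list(p = p_new, v = v, hit = FALSE))
  dd <- p_new - p_old
  A <- sum(dd^2)
  B <- sum(p_old * dd)
  C <- sum(p_old^2) - R2
  t <- (-B + sqrt(max(B^2 - A * C, 0))) / A
  cross <- p_old + t * dd
  n <- cross / arena_radius
  rem <- (1 - t) * dd
  rem <- rem - 2 * sum(rem * n) * n
  p <- cross + rem
  v <- v - 2 * sum(v * n) * n
  if (sum(p^2) > R2) p <- p * (arena_radius / sqrt(sum(p^2))) # pathological overshoot
  list(p = p, v = v, hit = TRUE)
}

contain_clamp <- function(p_new, arena_radius) {
  m <- sqrt(sum(p_new^2))
  if (m <= arena_radius) p_new else p_new * (arena_radius / m)
}

#' One synchronous model step
#'
#' Advance all particles by one time step from a common pre-update state:
#' for each particle the desired heading is the repulsion heading if any
#' neighbour sits inside the zone of repulsion (absolute priority) and the
#' alignment heading otherwise; the speed is v0 * psi^gamma from the local
#' order psi; the Gaussian noise rotation is applied first and the
#' wall-avoidance rotation second (evaluated on the post-noise heading);
#' positions are then streamed by r(t + dt) = r(t) + V dt and containment
#' keeps every particle inside the arena.
#'
#' Draws `n_particles` standard normal variates from the current RNG stream
#' (one per particle, in index order), identically to the compiled run loop.
#'
#' @param state a [particle_state()].
#' @param params an [spp_params()].
#' @return the updated `particle_state`.
#' @export
spp_step <- function(state, params) {
  n <- nrow(state$positions)
  xi <- rnorm(n, 0, 1) * params$eta
  new_pos <- state$positions
  new_vel <- state$velocities
  new_head <- state$headings
  for (i in seq_len(n)) {
    u <- repulsion_heading(i, state, params$zor_radius)
    if (is.null(u)) u <- alignment_heading(i, state, params$zoa_radius)
    psi <- local_order(i, state, params$zor_radius, zoa_radius = params$zoa_radius)
    sp <- update_speed(min(psi, 1), params$v0, params$gamma)
    ang <- atan2(u[2], u[1]) + xi[i]
    ang <- ang + wall_rotation(state$positions[i, ], heading_vec(ang),
                               params$v0, params$arena_radius)
    v <- sp * heading_vec(ang)
    p <- state$positions[i, ] + v * params$dt
    if (params$containment_mode == "reflect") {
      ct <- contain_reflect(state$positions[i, ], p, v, params$arena_radius)
      p <- ct$p
      v <- ct$v
      if (ct$hit && sp > 0) ang <- atan2(v[2], v[1])
    } else {
      p <- contain_clamp(p, params$arena_radius)
    }
    new_pos[i, ] <- p
    new_vel[i, ] <- v
    new_head[i] <- ang
  }
  particle_state(new_pos, new_vel, new_head,
                 time_index = state$time_index + 1L)
}
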