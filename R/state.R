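#' Instantaneous particle state
#'
#' Positions, velocities and headings of all N particles at one time step.
#' A particle always carries a heading angle, even at zero speed; whenever
#' the speed is positive the heading is the direction of the velocity.
#'
#' @param positions N x 2 matrix of planar coordinates (arena-centred).
#' @param velocities N x 2 matrix of planar velocity vectors; optional if
#'   `headings` (and `speeds`) are given.
#' @param headings length-N vector of heading angles in radians; derived
#'   from the velocities when omitted (zero-velocity rows get heading 0).
#' @param speeds length-N speeds used to build velocities when only
#'   headings are supplied (default 0).
#' @param time_index integer frame index (default 0).
#' @return object of class `particle_state`.
#' @export
particle_state <- function(positions, velocities = NULL, headings = NULL,
                           speeds = 0, time_index = 0L) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 2, all(is.finite(positions)))
  n <- nrow(positions)
  if (is.null(velocities) && is.null(headings))
    stop("supply velocities, headings, or both")
  if (is.null(velocities)) {
    stopifnot(length(headings) == n)
    speeds <- rep_len(speeds, n)
    velocities <- cbind(speeds * cos(headings), speeds * sin(headings))
  } else {
    velocities <- as.matrix(velocities)
    stopifnot(nrow(velocities) == n, ncol(velocities) == 2)
    if (is.null(headings)) {
      headings <- atan2(velocities[, 2], velocities[, 1])
      headings[rowSums(velocities^2) == 0] <- 0
    }
  }
  structure(
    list(positions = positions, velocities = velocities,
         headings = as.numeric(headings), time_index = as.integer(time_index)),
    class = "particle_state"
  )
}

#' @export
print.particle_state <- function(x, ...) {
  cat(sprintf("particle_state: %d particles at t = %d\n",
              nrow(x$positions), x$time_index))
  invisible(x)
}
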