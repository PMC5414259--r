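# Trajectory container shared by the simulator, the synthetic generators and
# every analysis routine. Frames are rows of the coordinate matrices; NA
# cells mark individuals missing from a frame (imperfect tracking).

new_trajectory <- function(x, y, vx = NULL, vy = NULL, heading = NULL,
                           params = list(), seed = NA_integer_,
                           frame_index = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(all(dim(x) == dim(y)))
  if (is.null(frame_index)) frame_index <- seq_len(nrow(x)) - 1L
  if (is.null(heading) && !is.null(vx)) {
    heading <- atan2(vy, vx)
    heading[!is.na(vx) & vx == 0 & vy == 0] <- 0
  }
  structure(
    list(x = x, y = y, vx = vx, vy = vy, heading = heading,
         params = params, seed = seed, frame_index = as.integer(frame_index)),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d individuals%s\n",
              nrow(x$x), ncol(x$x),
              if (anyNA(x$x)) " (with missing observations)" else ""))
  if (!is.null(x$params$arena_radius))
    cat(sprintf("  arena radius %g\n", x$params$arena_radius))
  if (!is.na(x$seed)) cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Number of frames / individuals of a trajectory
#' @param traj a trajectory.
#' @return integer count.
#' @export
n_frames <- function(traj) nrow(traj$x)

#' @rdname n_frames
#' @export
n_individuals <- function(traj) ncol(traj$x)

#' Long-format view of a trajectory
#'
#' @param x a trajectory.
#' @param row.names,optional,... passed over from the generic (unused).
#' @return data.frame with columns frame, id, x, y and, when available,
#'   vx, vy. Missing observations are dropped.
#' @export
as.data.frame.trajectory <- function(x, row.names = NULL, optional = FALSE, ...) {
  nf <- nrow(x$x); n <- ncol(x$x)
  d <- data.frame(
    frame = rep(x$frame_index, times = n),
    id = rep(seq_len(n) - 1L, each = nf),
    x = as.vector(x$x),
    y = as.vector(x$y)
  )
  if (!is.null(x$vx)) {
    d$vx <- as.vector(x$vx)
    d$vy <- as.vector(x$vy)
  }
  d <- d[!is.na(d$x) & !is.na(d$y), , drop = FALSE]
  d <- d[order(d$frame, d$id), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Concatenate trajectories frame-wise
#'
#' Stack the frames of several trajectories over the same arena and the
#' same number of individuals (e.g. independent replicate runs) into one
#' trajectory, so their statistics can be pooled.
#'
#' @param ... trajectories, or a single list of trajectories.
#' @return the pooled trajectory (parameters taken from the first).
#' @export
bind_trajectories <- function(...) {
  trs <- list(...)
  if (length(trs) == 1 && !inherits(trs[[1]], "trajectory")) trs <- trs[[1]]
  stopifnot(length(trs) >= 1, all(vapply(trs, inherits, TRUE, "trajectory")))
  n <- unique(vapply(trs, n_individuals, 1L))
  if (length(n) != 1) stop("trajectories have different numbers of individuals")
  out <- trs[[1]]
  for (f in c("x", "y", "vx", "vy", "heading")) {
    if (is.null(out[[f]])) next
    out[[f]] <- do.call(rbind, lapply(trs, `[[`, f))
  }
  out$frame_index <- seq_len(nrow(out$x)) - 1L
  out
}

# positions of one frame as a complete-case N x 2 matrix
frame_positions <- function(traj, f) {
  p <- cbind(traj$x[f, ], traj$y[f, ])
  p[stats::complete.cases(p), , drop = FALSE]
}

# heading angles of one frame (NA-free)
frame_headings <- function(traj, f) {
  if (!is.null(traj$heading)) {
    th <- traj$heading[f, ]
  } else if (!is.null(traj$vx)) {
    th <- atan2(traj$vy[f, ], traj$vx[f, ])
  } else {
    stop("trajectory carries neither headings nor velocities")
  }
  th[!is.na(th)]
}
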