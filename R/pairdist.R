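#' Radial pair distribution function
#'
#' Histogram of all ordered pair separations, accumulated over frames and
#' normalized against the ideal-gas reference so that g(r) measures how the
#' local density around an individual compares with the average density:
#' g > 1 indicates aggregation at that separation.
#'
#' Two normalizations are available. `"shell"` divides each bin by the
#' annulus area 2 pi r dr relative to the arena area (the textbook
#' expression), which in a bounded arena decays below 1 at large r because
#' part of the annulus falls outside the wall. `"edge_corrected"` (default)
#' divides by the exact expected ideal-gas pair count per bin for uniform
#' points in the arena disc ([disc_pair_density()]), so a spatially uniform
#' ensemble gives g = 1 at every separation -- the property the Boltzmann
#' inversion relies on.
#'
#' @param traj a trajectory (or any object with `x`/`y` frame matrices).
#' @param params an [analysis_params()]; its `arena_radius` must match the
#'   trajectory's arena.
#' @return g-kind [radial_profile()]; `count` holds raw ordered pair tallies
#'   (summing to N (N - 1) per complete frame when `r_max` spans the arena
#'   diameter).
#' @export
pair_distribution <- function(traj, params = analysis_params()) {
  stopifnot(inherits(params, "analysis_params"))
  h <- params$bin_width
  R <- params$arena_radius
  nb <- as.integer(floor(params$r_max / h + 1e-9))
  if (nb < 1) stop("r_max smaller than one bin")
  breaks <- h * (0:nb)
  nf <- n_frames(traj)
  if (nf < 1) stop("need at least one frame")

  counts <- numeric(nb)      # unordered tallies, doubled at the end
  sum_nn1 <- 0               # accumulated N (N - 1) over frames
  complete <- !anyNA(traj$x) && !anyNA(traj$y)
  n <- n_individuals(traj)
  if (complete && n < 2) stop("need at least two individuals")

  if (complete && n * (n - 1) / 2 <= nf) {
    # few particles, many frames: vectorize over frames for each pair
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- sqrt((traj$x[, i] - traj$x[, j])^2 + (traj$y[, i] - traj$y[, j])^2)
        idx <- pmax(1L, as.integer(ceiling(d / h - 1e-9)))
        counts <- counts + tabulate(idx[idx <= nb], nbins = nb)
      }
    }
    sum_nn1 <- nf * n * (n - 1)
  } else {
    for (f in seq_len(nf)) {
      p <- frame_positions(traj, f)
      nfp <- nrow(p)
      sum_nn1 <- sum_nn1 + nfp * (nfp - 1)
      if (nfp < 2) next
      d <- as.vector(stats::dist(p))
      idx <- pmax(1L, as.integer(ceiling(d / h - 1e-9)))
      counts <- counts + tabulate(idx[idx <= nb], nbins = nb)
    }
    if (sum_nn1 == 0) stop("need at least two individuals")
  }
  counts <- 2 * counts  # ordered pairs, as in the double-sum definition

  mass <- switch(params$normalization_mode,
    shell = {
      centers <- (breaks[-1] + breaks[-(nb + 1)]) / 2
      2 * pi * centers * h / (pi * R^2)
    },
    edge_corrected = disc_pair_bin_mass(breaks, R)
  )
  expected <- sum_nn1 * mass
  g <- ifelse(expected > 0, counts / expected, 0)
  prof <- radial_profile((breaks[-1] + breaks[-(nb + 1)]) / 2, g, counts,
                         kind = "g")
  attr(prof, "expected") <- expected
  attr(prof, "params") <- unclass(params)
  prof
}

#' Full inversion pipeline for a trajectory
#'
#' Convenience chain used for simulator output: pair distribution function
#' (edge-corrected by default), moving-average smoothing, plateau
#' rescaling, direct Boltzmann inversion, and the mean interaction force.
#'
#' @param traj a trajectory.
#' @param params an [analysis_params()].
#' @param rescale rescale the smoothed g so its large-r plateau is 1 before
#'   inversion (default TRUE).
#' @return list with elements `g` (raw), `g_smooth`, `U`, `F` and `stats`
#'   (the [group_stats()] row).
#' @export
school_analysis <- function(traj, params = analysis_params(), rescale = TRUE) {
  g <- pair_distribution(traj, params)
  gs <- smooth_profile(g, params$smoothing_window)
  if (rescale) gs <- normalize_plateau(gs)
  U <- boltzmann_invert(gs, params$kBT)
  Fp <- mean_force(U)
  list(g = g, g_smooth = gs, U = U, F = Fp, stats = group_stats(traj))
}
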