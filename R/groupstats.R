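# Scalar observables per run: area, density, packing fraction, polar order,
# and the angular occupancy map of the arena.

#' Number density of a group
#'
#' rho = N / A with A the area covered by the group.
#'
#' @param n number of individuals.
#' @param area group area (> 0 unless n = 0).
#' @return individuals per unit area.
#' @export
number_density <- function(n, area) {
  stopifnot(n >= 0)
  if (n == 0) return(0)
  if (!is.numeric(area) || area <= 0) stop("area must be positive")
  n / area
}

#' Packing fraction of a group
#'
#' Ratio a = A_f / A between the summed body area of all individuals and the
#' group's (convex-hull) area. Values near 0 are gas-like; a warning is
#' emitted above 1, which can only occur when bodies overlap.
#'
#' @param body_areas per-individual body areas (recycled scalar allowed);
#'   see [body_area_ellipse()] for the default body model.
#' @param n number of individuals (defaults to `length(body_areas)`).
#' @param area group area.
#' @return dimensionless packing fraction.
#' @export
packing_fraction <- function(body_areas, area, n = NULL) {
  if (!is.numeric(area) || area <= 0) stop("area must be positive")
  if (!is.null(n)) body_areas <- rep_len(body_areas, n)
  a <- sum(body_areas) / area
  if (a >= 1)
    warning("packing fraction reaches or exceeds 1; overlapping bodies")
  a
}

#' Polar order parameter
#'
#' phi = < (1/N) | sum_j exp(i theta_j) | >, the time-averaged magnitude of
#' the mean heading unit vector: 1 for a perfectly aligned group, 0 for
#' complete cancellation.
#'
#' @param headings a trajectory, or a matrix of heading angles
#'   (frames x individuals), or a single frame's vector of angles.
#' @return phi in \[0, 1\].
#' @export
#' @examples
#' polar_order(c(0, 0, 0))       # 1
#' polar_order(c(0, pi))         # 0
polar_order <- function(headings) {
  if (inherits(headings, "trajectory")) {
    traj <- headings
    vals <- vapply(seq_len(n_frames(traj)), function(f) {
      th <- frame_headings(traj, f)
      if (length(th) == 0) return(NA_real_)
      sqrt(mean(cos(th))^2 + mean(sin(th))^2)
    }, numeric(1))
    if (anyNA(vals)) {
      warning("empty frames skipped in polar order average")
      vals <- vals[!is.na(vals)]
    }
    return(mean(vals))
  }
  th <- if (is.matrix(headings)) headings else matrix(headings, nrow = 1)
  vals <- apply(th, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_real_)
    sqrt(mean(cos(v))^2 + mean(sin(v))^2)
  })
  if (anyNA(vals)) {
    warning("empty frames skipped in polar order average")
    vals <- vals[!is.na(vals)]
  }
  mean(vals)
}

#' Group statistics of a trajectory
#'
#' Time-averaged convex-hull area, number density rho = N / A, packing
#' fraction (when a body model is supplied) and polar order parameter.
#'
#' @param traj a trajectory.
#' @param body_length optional body length; with `body_area` absent, the
#'   elliptical body model [body_area_ellipse()] is used.
#' @param body_area optional per-individual body area (overrides
#'   `body_length`).
#' @return one-row data.frame with columns `area`, `density`,
#'   `packing_fraction` (NA without a body model) and `polar_order`.
#' @export
group_stats <- function(traj, body_length = NULL, body_area = NULL) {
  nf <- n_frames(traj)
  areas <- vapply(seq_len(nf), function(f) {
    p <- frame_positions(traj, f)
    if (nrow(p) < 3) return(NA_real_)
    tryCatch(group_area(p), error = function(e) NA_real_)
  }, numeric(1))
  area <- mean(areas, na.rm = TRUE)
  n_mean <- mean(vapply(seq_len(nf),
                        function(f) nrow(frame_positions(traj, f)), numeric(1)))
  dens <- number_density(n_mean, area)
  pf <- NA_real_
  if (!is.null(body_area) || !is.null(body_length)) {
    if (is.null(body_area)) body_area <- body_area_ellipse(body_length)
    pf <- packing_fraction(body_area, area, n = round(n_mean))
  }
  data.frame(area = area, density = dens, packing_fraction = pf,
             polar_order = polar_order(traj))
}

#' Angular occupancy of the arena
#'
#' Count individuals per angular segment of the arena and per block of
#' consecutive frames, the raster representation of how a group sweeps the
#' arena over time. Angles are measured counterclockwise from the positive
#' x axis.
#'
#' @param traj a trajectory.
#' @param segment_degrees angular width of a segment; must divide 360
#'   (default 20).
#' @param frames_per_bin frames aggregated into one time bin (default 1; at
#'   the default frame rate of 1 step this is one time unit per column).
#' @return integer matrix, one row per angular segment (labelled by its
#'   lower edge) and one column per time bin. With complete observations
#'   every column sums to N * frames_per_bin.
#' @export
angular_occupancy <- function(traj, segment_degrees = 20, frames_per_bin = 1L) {
  if (360 %% segment_degrees != 0)
    stop("segment_degrees must divide 360 evenly")
  n_seg <- as.integer(360 / segment_degrees)
  nf <- n_frames(traj)
  n_bin <- nf %/% frames_per_bin
  if (n_bin == 0 || nf == 0) {
    return(matrix(integer(0), nrow = n_seg, ncol = 0,
                  dimnames = list(paste0(seq_len(n_seg) - 1L, "*", segment_degrees, "deg"), NULL)))
  }
  if (nf %% frames_per_bin != 0)
    warning("incomplete final time bin dropped")
  m <- matrix(0L, nrow = n_seg, ncol = n_bin)
  for (b in seq_len(n_bin)) {
    fr <- ((b - 1L) * frames_per_bin + 1L):(b * frames_per_bin)
    ang <- atan2(traj$y[fr, , drop = FALSE], traj$x[fr, , drop = FALSE])
    ang <- ang[!is.na(ang)]
    deg <- (ang * 180 / pi) %% 360
    idx <- pmin(floor(deg / segment_degrees) + 1L, n_seg)
    m[, b] <- tabulate(idx, nbins = n_seg)
  }
  rownames(m) <- sprintf("[%g,%g)", (seq_len(n_seg) - 1L) * segment_degrees,
                         seq_len(n_seg) * segment_degrees)
  colnames(m) <- sprintf("t%d", seq_len(n_bin) - 1L)
  m
}
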