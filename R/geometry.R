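# Disc geometry used by the edge-corrected pair-distribution normalization.

#' Pair-distance density of uniform points in a disc
#'
#' Probability density of the distance between two independent points drawn
#' uniformly from a disc of radius `R` (the "disk line picking" law),
#' supported on \[0, 2R\]:
#' f(r) = (4 r / (pi R^2)) acos(r / 2R) - (2 r^2 / (pi R^3)) sqrt(1 - r^2/4R^2).
#' This is the exact ideal-gas reference against which g(r) is measured in a
#' bounded circular arena.
#'
#' @param r distances (vectorized).
#' @param R disc radius.
#' @return density values (0 outside the support).
#' @export
disc_pair_density <- function(r, R) {
  out <- numeric(length(r))
  ok <- r >= 0 & r <= 2 * R
  s <- r[ok]
  out[ok] <- (4 * s / (pi * R^2)) * acos(pmin(s / (2 * R), 1)) -
    (2 * s^2 / (pi * R^3)) * sqrt(pmax(1 - s^2 / (4 * R^2), 0))
  out
}

# Probability mass of the ideal-gas pair distance in each histogram bin
# (Simpson's rule on a fine subgrid; exact to well below sampling error).
disc_pair_bin_mass <- function(breaks, R, n_sub = 32L) {
  nb <- length(breaks) - 1L
  mass <- numeric(nb)
  for (b in seq_len(nb)) {
    lo <- breaks[b]; hi <- breaks[b + 1L]
    xs <- seq(lo, hi, length.out = n_sub + 1L)
    fx <- disc_pair_density(xs, R)
    hsub <- (hi - lo) / n_sub
    w <- rep(c(2, 4), length.out = n_sub + 1L)
    w[1] <- 1; w[n_sub + 1L] <- 1
    mass[b] <- sum(w * fx) * hsub / 3
  }
  mass
}

shoelace_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Convex-hull area of a point configuration
#'
#' Area covered by a group of individuals, measured as the area of the
#' convex hull of their positions.
#'
#' @param points N x 2 matrix of positions (N >= 3, not all collinear).
#' @return hull area.
#' @export
#' @examples
#' group_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # 1
group_area <- function(points) {
  points <- as.matrix(points)
  points <- points[stats::complete.cases(points), , drop = FALSE]
  if (nrow(points) < 3)
    stop("convex hull needs at least 3 points")
  hull <- grDevices::chull(points)
  if (length(hull) < 3)
    stop("degenerate (collinear) configuration has no hull area")
  a <- shoelace_area(points[hull, , drop = FALSE])
  if (a == 0) stop("degenerate (collinear) configuration has no hull area")
  a
}
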