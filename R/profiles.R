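# Radial profiles: the common container for g(r), U(r) and F(r), the
# 5-point smoothing, plateau normalization, direct Boltzmann inversion and
# the finite-difference mean force.

#' Radial profile container
#'
#' A binned radial axis with values and per-bin pair tallies. `kind` is one
#' of `"g"` (pair distribution), `"U"` (potential of mean force) or `"F"`
#' (mean force). Undefined bins (e.g. U where g = 0) are NA.
#'
#' @param r strictly increasing, uniformly spaced bin centers.
#' @param value profile values (NA = undefined bin).
#' @param count per-bin tallies (ordered pair counts for `"g"`).
#' @param kind `"g"`, `"U"` or `"F"`.
#' @return object of class `radial_profile`.
#' @export
radial_profile <- function(r, value, count = rep(0, length(r)),
                           kind = c("g", "U", "F")) {
  kind <- match.arg(kind)
  stopifnot(length(r) == length(value), length(r) == length(count))
  if (length(r) > 1) {
    dr <- diff(r)
    if (any(dr <= 0) || max(abs(dr - dr[1])) > 1e-8 * dr[1])
      stop("bin centers must be strictly increasing and uniformly spaced")
  }
  if (kind == "g" && any(value < 0, na.rm = TRUE))
    stop("g values must be non-negative")
  structure(list(r = r, value = value, count = count, kind = kind),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  def <- sum(!is.na(x$value))
  cat(sprintf("radial_profile '%s': %d bins (%d defined), r in [%g, %g]\n",
              x$kind, length(x$r), def, min(x$r), max(x$r)))
  invisible(x)
}

#' @export
as.data.frame.radial_profile <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(r = x$r, value = x$value, count = x$count, kind = x$kind)
}

bin_spacing <- function(profile) {
  if (length(profile$r) < 2) stop("profile too short")
  profile$r[2] - profile$r[1]
}

#' Moving-average smoothing of a radial profile
#'
#' Centred moving average of odd width (5 points for the published
#' analysis); at the profile edges the window shrinks symmetrically. Counts
#' are propagated by summation over the same windows.
#'
#' @param profile a [radial_profile()].
#' @param window odd window width, at most the profile length.
#' @return smoothed profile of the same kind.
#' @export
smooth_profile <- function(profile, window = 5L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("smoothing window must be odd")
  n <- length(profile$value)
  if (window > n) stop("smoothing window exceeds profile length")
  half <- window %/% 2L
  v <- numeric(n)
  cnt <- numeric(n)
  for (i in seq_len(n)) {
    w <- min(half, i - 1L, n - i)  # shrink symmetrically at edges
    idx <- (i - w):(i + w)
    v[i] <- mean(profile$value[idx])
    cnt[i] <- sum(profile$count[idx])
  }
  radial_profile(profile$r, v, cnt, kind = profile$kind)
}

#' Rescale g(r) so its large-r plateau is 1
#'
#' Divides the profile by the mean of its last quartile of defined bins.
#' Fixing the plateau at 1 pins the additive constant of the potential of
#' mean force at U(large r) = 0 and absorbs the partition function of the
#' underlying Boltzmann distribution.
#'
#' @param profile a g-kind [radial_profile()].
#' @param fraction trailing fraction of defined bins averaged (default 0.25).
#' @return rescaled profile.
#' @export
normalize_plateau <- function(profile, fraction = 0.25) {
  stopifnot(profile$kind == "g")
  def <- which(is.finite(profile$value) & profile$value > 0)
  if (length(def) == 0) stop("no defined bins")
  tail_idx <- def[def >= stats::quantile(def, 1 - fraction, type = 1)]
  plateau <- mean(profile$value[tail_idx])
  if (!is.finite(plateau) || plateau <= 0)
    stop("large-r plateau of g is not positive; cannot rescale")
  radial_profile(profile$r, profile$value / plateau, profile$count, kind = "g")
}

#' Direct Boltzmann inversion
#'
#' Estimate the potential of mean force from a pair distribution function
#' under the assumption that configurations are drawn from a Boltzmann
#' distribution: U(r) = -kBT log g(r). Bins with g = 0 are undefined (NA)
#' and break the profile into segments; the additive constant is fixed
#' implicitly by g -> 1 giving U -> 0.
#'
#' @param g a g-kind [radial_profile()].
#' @param kBT energy scale (default 1; the inverse temperature here is a
#'   bookkeeping constant, not a thermodynamic temperature).
#' @return U-kind [radial_profile()].
#' @export
#' @examples
#' g <- radial_profile(1:5, c(1, exp(-1), 1, 1, 1), kind = "g")
#' boltzmann_invert(g)$value   # 0, 1, 0, 0, 0
boltzmann_invert <- function(g, kBT = 1) {
  stopifnot(inherits(g, "radial_profile"), g$kind == "g", kBT > 0)
  if (all(!is.finite(g$value) | g$value == 0))
    stop("all bins of g are zero or undefined; nothing to invert")
  U <- ifelse(is.finite(g$value) & g$value > 0, -kBT * log(g$value), NA_real_)
  radial_profile(g$r, U, g$count, kind = "U")
}

# maximal runs of consecutive defined bins
defined_segments <- function(v) {
  def <- is.finite(v)
  r <- rle(def)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  Map(function(s, e) s:e, starts[r$values], ends[r$values])
}

#' Mean interaction force
#'
#' F(r) = -dU/dr by central finite differences on the interior bins of each
#' contiguous defined segment of U, with one-sided differences at segment
#' ends; never differenced across gaps (bins where g was 0). Positive force
#' is repulsive, negative is attractive.
#'
#' @param U a U-kind [radial_profile()] with at least 3 consecutive defined
#'   bins.
#' @return F-kind [radial_profile()].
#' @export
mean_force <- function(U) {
  stopifnot(inherits(U, "radial_profile"), U$kind == "U")
  h <- bin_spacing(U)
  segs <- defined_segments(U$value)
  segs <- segs[vapply(segs, length, 1L) >= 3L]
  if (length(segs) == 0)
    stop("mean force needs at least 3 consecutive defined bins of U")
  Fv <- rep(NA_real_, length(U$value))
  for (idx in segs) {
    u <- U$value[idx]
    n <- length(idx)
    f <- numeric(n)
    f[1] <- -(u[2] - u[1]) / h
    f[n] <- -(u[n] - u[n - 1]) / h
    if (n > 2) f[2:(n - 1)] <- -(u[3:n] - u[1:(n - 2)]) / (2 * h)
    Fv[idx] <- f
  }
  radial_profile(U$r, Fv, U$count, kind = "F")
}

#' Location of the minimum of a potential profile
#'
#' Effective potentials inferred from finite samples can have flat minima;
#' the bin-wise argmin is then dominated by noise. This reports the centre
#' of the minimal basin: the mean bin centre over all bins within
#' `tolerance` energy units of the minimum.
#'
#' @param U a U-kind [radial_profile()].
#' @param tolerance basin depth above the minimum included (default 0.05).
#' @return radius of the basin centre.
#' @export
u_min_radius <- function(U, tolerance = 0.05) {
  stopifnot(inherits(U, "radial_profile"), U$kind == "U")
  if (all(!is.finite(U$value))) stop("U has no defined bins")
  lo <- min(U$value, na.rm = TRUE)
  mean(U$r[which(is.finite(U$value) & U$value <= lo + tolerance)])
}

#' Peak and half-radial width of g(r)
#'
#' Locate the main density peak of a pair distribution function and the
#' aggregation extent: `peak_radius` is the bin center of the maximum of g
#' (smallest radius on ties), `peak_value` its height, and
#' `half_radial_width` the largest radius beyond the peak at which g crosses
#' the uniform baseline g = 1 from above (linearly interpolated between bin
#' centers; NA when g never exceeds 1).
#'
#' @param g a g-kind [radial_profile()] with at least 3 defined bins.
#' @return list with `peak_radius`, `peak_value`, `half_radial_width`.
#' @export
profile_features <- function(g) {
  stopifnot(inherits(g, "radial_profile"), g$kind == "g")
  def <- which(is.finite(g$value))
  if (length(def) < 3) stop("profile needs at least 3 defined bins")
  v <- g$value
  if (max(v[def]) == min(v[def]))
    stop("flat profile has no peak")
  ipk <- def[which.max(v[def])]  # which.max takes the first (smallest r) tie
  if (v[ipk] <= 1) {
    return(list(peak_radius = g$r[ipk], peak_value = v[ipk],
                half_radial_width = NA_real_))
  }
  hw <- NA_real_
  after <- def[def >= ipk]
  for (j in seq_along(after)[-length(after)]) {
    i1 <- after[j]; i2 <- after[j + 1L]
    if (i2 != i1 + 1L) next
    if (v[i1] > 1 && v[i2] <= 1) {
      hw <- g$r[i1] + (v[i1] - 1) / (v[i1] - v[i2]) * (g$r[i2] - g$r[i1])
    }
  }
  list(peak_radius = g$r[ipk], peak_value = v[ipk], half_radial_width = hw)
}
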