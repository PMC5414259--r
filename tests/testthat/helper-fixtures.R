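# Shared helpers for building small states and thinning trajectories.

# a particle_state from positions (list/matrix) and heading angles
make_state <- function(pos, headings, speeds = 1) {
  particle_state(as.matrix(pos), headings = headings, speeds = speeds)
}

# keep every by-th frame of a trajectory (pair statistics of consecutive
# simulator frames are strongly autocorrelated)
thin_traj <- function(tr, by = 10) {
  idx <- seq(1, n_frames(tr), by = by)
  for (f in c("x", "y", "vx", "vy", "heading"))
    if (!is.null(tr[[f]])) tr[[f]] <- tr[[f]][idx, , drop = FALSE]
  tr$frame_index <- tr$frame_index[idx]
  tr
}

# absolute angular difference on the circle
ang_dist <- function(a, b) abs(atan2(sin(a - b), cos(a - b)))

# per-bin mean and standard error of g over consecutive frame blocks
# (captures the correlation between pairs sharing a particle, which a
# Poisson count model misses)
block_g <- function(traj, params, n_blocks = 50) {
  nf <- n_frames(traj)
  cuts <- split(seq_len(nf), cut(seq_len(nf), n_blocks, labels = FALSE))
  vals <- sapply(cuts, function(idx) {
    sub <- traj
    for (f in c("x", "y")) sub[[f]] <- sub[[f]][idx, , drop = FALSE]
    sub$frame_index <- sub$frame_index[idx]
    pair_distribution(sub, params)$value
  })
  g <- pair_distribution(traj, params)
  list(r = g$r, count = g$count, mean = rowMeans(vals),
       se = apply(vals, 1, stats::sd) / sqrt(length(cuts)))
}

# empirical CDF of the uniform-disc pair-distance law, by fine-grid
# integration of the closed-form density (independent of the package's
# per-bin Simpson masses)
disc_pair_cdf <- function(R) {
  r <- seq(0, 2 * R, length.out = 8192)
  f <- (4 * r / (pi * R^2)) * acos(pmin(r / (2 * R), 1)) -
    (2 * r^2 / (pi * R^3)) * sqrt(pmax(1 - r^2 / (4 * R^2), 0))
  cdf <- cumsum(f) * (r[2] - r[1])
  cdf <- cdf / cdf[length(cdf)]
  stats::approxfun(r, cdf, yleft = 0, yright = 1)
}
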