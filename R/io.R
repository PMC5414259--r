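# Delimited-text interchange: trajectories as long CSV (frame, id, x, y,
# vx, vy) with a JSON sidecar for parameters, radial profiles as CSV, and a
# JSON run manifest that makes every output reproducible.

#' Write / read a trajectory CSV
#'
#' The on-disk format is one row per individual per frame with columns
#' `frame, id, x, y, vx, vy` (velocities omitted when the trajectory has
#' none) and a JSON sidecar `<path>.json` carrying the parameters and seed.
#' Files produced by external tracking are accepted too: the header must
#' match, velocity columns may be absent (headings are then derived from
#' frame-to-frame displacements), rows with non-finite coordinates are
#' dropped with a count reported, and individuals missing from some frames
#' are tolerated with a warning.
#'
#' @param traj a trajectory.
#' @param path CSV file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a trajectory.
#' @export
write_trajectory <- function(traj, path) {
  d <- as.data.frame(traj)
  write.csv(d, path, row.names = FALSE)
  meta <- list(params = traj$params, seed = traj$seed,
               package_version = as.character(packageVersion("pmfish")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @param dt frame spacing used to derive velocities from displacements
#'   when the file has no velocity columns (default 1).
#' @export
read_trajectory <- function(path, dt = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.csv(path)
  need <- c("frame", "id", "x", "y")
  if (!all(need %in% names(d)))
    stop("trajectory header must contain columns: ", paste(need, collapse = ", "))
  has_v <- all(c("vx", "vy") %in% names(d))
  bad <- !is.finite(d$x) | !is.finite(d$y)
  if (any(bad)) {
    warning(sprintf("%d rows with non-finite coordinates dropped", sum(bad)))
    d <- d[!bad, , drop = FALSE]
  }
  if (nrow(d) == 0) stop("no usable rows in ", path)
  frames <- sort(unique(d$frame))
  ids <- sort(unique(d$id))
  nf <- length(frames); n <- length(ids)
  if (nrow(d) < nf * n)
    warning("individual count varies across frames; missing observations set to NA")
  fi <- match(d$frame, frames)
  ii <- match(d$id, ids)
  idx <- cbind(fi, ii)
  x <- matrix(NA_real_, nf, n); y <- x
  x[idx] <- d$x; y[idx] <- d$y
  vx <- vy <- NULL
  if (has_v) {
    vx <- matrix(NA_real_, nf, n); vy <- vx
    vx[idx] <- d$vx; vy[idx] <- d$vy
  } else if (nf >= 2) {
    # headings from forward displacements; last frame repeats the previous
    vx <- (rbind(x[-1, , drop = FALSE], x[nf, , drop = FALSE]) - x) / dt
    vy <- (rbind(y[-1, , drop = FALSE], y[nf, , drop = FALSE]) - y) / dt
    vx[nf, ] <- vx[nf - 1, ]
    vy[nf, ] <- vy[nf - 1, ]
  }
  params <- list()
  seed <- NA_integer_
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$params)) params <- meta$params
    if (!is.null(meta$seed) && length(meta$seed)) seed <- as.integer(meta$seed)
  }
  new_trajectory(x, y, vx, vy, params = params, seed = seed,
                 frame_index = frames)
}

#' Write / read a radial profile CSV
#'
#' Columns `r, value, count, kind`; undefined bins round-trip as empty
#' `value` fields.
#'
#' @param profile a [radial_profile()].
#' @param path CSV file path.
#' @return `write_profile` returns `path` invisibly; `read_profile` a
#'   [radial_profile()].
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "radial_profile"))
  if (length(profile$r) == 0) stop("refusing to write an empty profile")
  write.csv(as.data.frame(profile), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- tryCatch(read.csv(path),
                error = function(e) stop("malformed profile file: ",
                                         conditionMessage(e)))
  need <- c("r", "value", "count", "kind")
  if (!all(need %in% names(d)))
    stop("profile header must contain columns: ", paste(need, collapse = ", "))
  kind <- unique(as.character(d$kind))
  if (length(kind) != 1 || !kind %in% c("g", "U", "F"))
    stop("profile kind column must be a single value among g, U, F (line 2)")
  radial_profile(d$r, d$value, d$count, kind = kind)
}

#' Write a run manifest
#'
#' JSON record of a command, its full parameter set, seed, package version
#' and timestamp -- enough to reproduce the run exactly.
#'
#' @param command name of the command or function run.
#' @param params full parameter set (list).
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @param file manifest file name (default `manifest.json`).
#' @return path of the manifest, invisibly.
#' @export
run_manifest <- function(command, params, seed, dir,
                         file = "manifest.json") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, file)
  jsonlite::write_json(
    list(command = command, params = params, seed = seed,
         code_version = as.character(packageVersion("pmfish")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
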