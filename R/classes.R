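#' Parameters for a fish size class
#'
#' The three developmental size classes (body lengths 7.5, 13 and 23 mm) are
#' modelled by scaling two quantities with body length: the alignment zone,
#' via the factor k = L / 7.5 rounded to two digits (1, 1.73, 3.07), and the
#' maximal speed, via v0 = b * v0e with the behavioural reaction time
#' b = 0.05 s and a class cruising speed v0e proportional to body length
#' (`v0e_per_k` mm/s for the smallest class; fish cruising speed scales
#' roughly linearly with body length). The repulsion zone is the same for
#' all classes.
#'
#' @param size_class `"small"`, `"medium"` or `"large"`.
#' @param v0e_per_k experimental cruising speed of the reference (small)
#'   class in mm/s (default 100).
#' @param b behavioural reaction time in seconds (default 0.05).
#' @param ... further arguments passed to [spp_params()] (e.g.
#'   `n_particles`, `n_steps`, `seed`).
#' @return an [spp_params()] object with class-specific `k` and `v0`.
#' @export
#' @examples
#' size_class_params("large", n_particles = 10, n_steps = 1000)$k  # 3.07
size_class_params <- function(size_class = c("small", "medium", "large"),
                              v0e_per_k = 100, b = 0.05, ...) {
  size_class <- match.arg(size_class)
  L <- c(small = 7.5, medium = 13, large = 23)[[size_class]]
  k <- body_size_scale(L)
  spp_params(k = k, v0 = calibrate_v0(b, v0e_per_k * k), ...)
}
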