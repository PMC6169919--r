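#' Idealized annular cross-section of the femoral mid-diaphysis
#'
#' All stress intensity computations treat the cortex at the notch plane as a
#' thick-walled circular cylinder. The section is parameterized by its outer
#' and inner radii; mean radius and wall thickness are derived.
#'
#' @param outer_radius Outer (periosteal) radius R_o in mm.
#' @param inner_radius Inner (endosteal) radius R_i in mm.
#' @return An object of class `cross_section` with fields `R_o`, `R_i`,
#'   `R_m` (mean radius, mm), `t` (wall thickness, mm) and `ratio` (R_m/t).
#' @examples
#' cross_section(0.9, 0.7)
#' @export
cross_section <- function(outer_radius, inner_radius) {
  if (!is.numeric(outer_radius) || !is.numeric(inner_radius) ||
      length(outer_radius) != 1L || length(inner_radius) != 1L ||
      !is.finite(outer_radius) || !is.finite(inner_radius)) {
    stop("outer_radius and inner_radius must be single finite numbers")
  }
  if (inner_radius <= 0 || outer_radius <= inner_radius) {
    stop("geometry error: need outer_radius > inner_radius > 0")
  }
  R_m <- (outer_radius + inner_radius) / 2
  t <- outer_radius - inner_radius
  if (R_m / t <= 1) {
    stop("geometry error: mean radius must exceed wall thickness (R_m/t > 1)")
  }
  structure(
    list(R_o = outer_radius, R_i = inner_radius, R_m = R_m, t = t,
         ratio = R_m / t),
    class = "cross_section"
  )
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf(
    "<cross_section> R_o = %.3f mm, R_i = %.3f mm, R_m = %.3f mm, t = %.3f mm (R_m/t = %.2f)\n",
    x$R_o, x$R_i, x$R_m, x$t, x$ratio))
  invisible(x)
}

#' Notch geometry of the machined starter crack
#'
#' The anterior notch is idealized as a symmetric circumferential through-wall
#' crack subtending a half angle `theta0` at the section centroid.
#'
#' @param theta0 Initial half crack angle in radians; must lie in (0, pi/2).
#' @param depth Notch depth in mm (recorded metadata; a two-stage saw + razor
#'   notch totals about 0.65 mm, but specimen-specific values are accepted).
#' @return Object of class `notch_geometry`.
#' @export
notch_geometry <- function(theta0, depth = NA_real_) {
  if (!is.numeric(theta0) || length(theta0) != 1L || !is.finite(theta0)) {
    stop("theta0 must be a single finite number")
  }
  if (theta0 <= 0 || theta0 >= pi / 2) {
    stop("geometry error: theta0 must lie in (0, pi/2)")
  }
  if (!is.na(depth) && depth <= 0) stop("notch depth must be positive")
  structure(list(theta0 = theta0, depth = depth), class = "notch_geometry")
}

#' Synchronized three-point-bend test record
#'
#' Bundles the test-frame load-displacement trace with the (typically sparser)
#' crack-extension series measured from side-view imaging frames. Load at the
#' imaging timestamps is obtained later by linear interpolation.
#'
#' @param time Load-trace timestamps in seconds, strictly increasing.
#' @param load Load in N, non-negative.
#' @param displacement Crosshead displacement in mm.
#' @param frame_time Imaging frame timestamps in seconds.
#' @param delta_a Projected crack extension per frame in mm, non-decreasing.
#' @param span Support span in mm (default 8).
#' @param pixel_size Image resolution in micrometres per pixel (default 2.2).
#' @return Object of class `bend_test_record`.
#' @export
bend_test_record <- function(time, load, displacement, frame_time, delta_a,
                             span = 8, pixel_size = 2.2) {
  if (length(time) != length(load) || length(time) != length(displacement)) {
    stop("time, load and displacement must have equal length")
  }
  if (length(frame_time) != length(delta_a)) {
    stop("frame_time and delta_a must have equal length")
  }
  if (any(!is.finite(time)) || any(!is.finite(load)) ||
      any(!is.finite(frame_time)) || any(!is.finite(delta_a))) {
    stop("input error: non-finite values in record")
  }
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (any(diff(frame_time) <= 0)) stop("frame_time must be strictly increasing")
  if (any(load < 0)) stop("input error: negative load")
  if (any(diff(delta_a) < -1e-12)) {
    stop("validation error: delta_a must be non-decreasing")
  }
  if (any(delta_a < 0)) stop("input error: negative crack extension")
  if (span <= 0 || pixel_size <= 0) stop("span and pixel_size must be positive")
  dur <- max(time) - min(time)
  if (dur > 60) {
    warning(sprintf("test duration %.1f s exceeds the plausible 60 s window", dur))
  }
  structure(
    list(time = as.numeric(time), load = as.numeric(load),
         displacement = as.numeric(displacement),
         frame_time = as.numeric(frame_time), delta_a = as.numeric(delta_a),
         span = span, pixel_size = pixel_size),
    class = "bend_test_record"
  )
}

#' @export
print.bend_test_record <- function(x, ...) {
  cat(sprintf(
    "<bend_test_record> %d load samples over %.1f s, %d frames, span %.1f mm, %.1f um/px\n",
    length(x$time), max(x$time) - min(x$time), length(x$frame_time),
    x$span, x$pixel_size))
  invisible(x)
}
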