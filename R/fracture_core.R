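# Core LEFM chain: surface crack extension -> half crack angle -> geometry
# factor -> stress intensity, plus event detection on the synchronized record
# and small-scale-yielding diagnostics.

#' Instantaneous half crack angle from projected surface crack extension
#'
#' Converts the projected crack extension measured on the medial bone surface
#' into the instantaneous half crack angle via the arc length at the mean
#' radius: theta = theta0 + delta_a / R_m. Values are clipped to (0, pi) with
#' a warning if the mapping overshoots.
#'
#' @param notch A [notch_geometry()].
#' @param delta_a Projected crack extension in mm, >= 0 (vectorized).
#' @param section A [cross_section()].
#' @return Half crack angle in radians.
#' @examples
#' half_crack_angle(notch_geometry(0.6), 0.08, cross_section(0.9, 0.7))
#' @export
half_crack_angle <- function(notch, delta_a, section) {
  stopifnot(inherits(notch, "notch_geometry"), inherits(section, "cross_section"))
  if (any(!is.finite(delta_a))) stop("input error: non-finite delta_a")
  if (any(delta_a < 0)) stop("input error: delta_a must be >= 0")
  theta <- notch$theta0 + delta_a / section$R_m
  hi <- pi - .Machine$double.eps^0.5
  if (any(theta >= hi)) {
    warning("half crack angle clipped below pi; crack consumed the section")
    theta <- pmin(theta, hi)
  }
  theta
}

#' Stress intensity factor for the cracked cylinder in three-point bending
#'
#' K = F_b * sigma_b * sqrt(pi * R_m * theta), with thin-walled-tube bending
#' stress sigma_b = M / (pi * R_m^2 * t) and mid-span moment M = P * S / 4.
#' Inputs are in lab units (N, mm); sigma_b is then in MPa and K is computed
#' in MPa*sqrt(mm) before conversion to MPa*sqrt(m) (factor 10^-1.5).
#'
#' @param load Applied load P in N (vectorized).
#' @param span Support span S in mm.
#' @param section A [cross_section()].
#' @param theta Half crack angle in radians (scalar or same length as load).
#' @param Fb Geometry factor; computed from `theta` and the section ratio when
#'   omitted.
#' @return Stress intensity in MPa*sqrt(m).
#' @examples
#' stress_intensity(10, 8, cross_section(0.9, 0.7), theta = 0.5)
#' @export
stress_intensity <- function(load, span, section, theta, Fb = NULL) {
  stopifnot(inherits(section, "cross_section"))
  if (any(!is.finite(load)) || !is.finite(span) || any(!is.finite(theta))) {
    stop("input error: non-finite arguments")
  }
  if (any(load < 0)) stop("input error: load must be >= 0")
  if (any(theta <= 0) || any(theta >= pi)) stop("theta must lie in (0, pi)")
  if (is.null(Fb)) Fb <- geometry_factor(theta, section$ratio)
  moment <- load * span / 4                           # N mm
  sigma_b <- moment / (pi * section$R_m^2 * section$t) # MPa
  k_mm <- Fb * sigma_b * sqrt(pi * section$R_m * theta) # MPa sqrt(mm)
  k_mm * 10^-1.5                                       # MPa sqrt(m)
}

#' Interpolate the load trace at the imaging frame timestamps
#'
#' @param record A [bend_test_record()].
#' @return Numeric vector of loads (N) at `record$frame_time`.
#' @export
frame_loads <- function(record) {
  stopifnot(inherits(record, "bend_test_record"))
  stats::approx(record$time, record$load, xout = record$frame_time,
                rule = 2)$y
}

#' Detect crack initiation, peak load and instability on a bend-test record
#'
#' Initiation is the first imaging frame whose projected crack extension
#' exceeds the detection threshold (default 5 pixels). Peak is the frame of
#' maximum interpolated load. Instability is the last frame before a
#' between-frame load drop exceeding `drop_frac` of the peak load; when no
#' such drop exists it falls back to the final frame with measurable crack
#' extension. The ordering initiation <= peak <= instability is enforced.
#'
#' @param record A [bend_test_record()].
#' @param init_threshold_px Crack-extension detection threshold in pixels
#'   (default 5; 11 micrometres at 2.2 um/px).
#' @param drop_frac Between-frame load drop, as a fraction of peak load, that
#'   marks unstable growth (default 0.10).
#' @return Object of class `event_triplet`: frame indices `initiation`,
#'   `peak`, `instability`, plus interpolated frame loads.
#' @export
detect_events <- function(record, init_threshold_px = 5, drop_frac = 0.10) {
  stopifnot(inherits(record, "bend_test_record"))
  if (init_threshold_px <= 0 || drop_frac <= 0) {
    stop("thresholds must be positive")
  }
  if (all(record$load == 0)) stop("input error: load trace is all zero")
  thr_mm <- init_threshold_px * record$pixel_size / 1000
  loads <- frame_loads(record)

  init <- which(record$delta_a > thr_mm)[1]
  if (is.na(init)) {
    stop(sprintf(
      "no initiation detected: crack extension never exceeds %.4f mm", thr_mm))
  }
  peak <- which.max(loads)
  pk <- loads[peak]

  drops <- -diff(loads)                 # positive where load falls
  big <- which(drops > drop_frac * pk)
  big <- big[big >= peak]               # unstable growth cannot precede peak
  if (length(big) > 0) {
    inst <- big[1]                      # last frame before the drop
  } else {
    inst <- max(which(record$delta_a > 0))
  }

  init <- min(init, peak)               # ordering invariant
  inst <- max(inst, peak)
  structure(
    list(initiation = init, peak = peak, instability = inst,
         frame_load = loads),
    class = "event_triplet"
  )
}

#' Fracture toughness triplet for one specimen
#'
#' Runs the full LEFM chain at the three detected loading events: interpolates
#' load at the event frames, maps crack extension to half crack angle,
#' evaluates the geometry factor and stress intensity, and attaches
#' small-scale-yielding validity diagnostics.
#'
#' @param record A [bend_test_record()].
#' @param notch A [notch_geometry()].
#' @param section A [cross_section()].
#' @param sigma_y Assumed tissue yield strength in MPa (default 160).
#' @param events Optional precomputed [detect_events()] result.
#' @param ... Passed to [detect_events()].
#' @return Object of class `toughness_result` with per-event K (MPa sqrt(m)),
#'   half crack angle theta (rad), load (N), frame index, and LEFM validity
#'   flag and plastic-zone ratio.
#' @export
toughness_triplet <- function(record, notch, section, sigma_y = 160,
                              events = NULL, ...) {
  if (is.null(events)) events <- detect_events(record, ...)
  idx <- c(init = events$initiation, pl = events$peak, inst = events$instability)
  load_ev <- events$frame_load[idx]
  da_ev <- record$delta_a[idx]
  theta_ev <- half_crack_angle(notch, da_ev, section)
  Fb_ev <- geometry_factor(theta_ev, section$ratio)
  K_ev <- stress_intensity(load_ev, record$span, section, theta_ev, Fb_ev)
  val <- lefm_validity(K_ev, section, sigma_y = sigma_y)
  structure(
    list(
      K_init = K_ev[[1]], K_pl = K_ev[[2]], K_inst = K_ev[[3]],
      events = data.frame(
        event = c("initiation", "peak", "instability"),
        frame = as.integer(idx), load_N = load_ev, delta_a_mm = da_ev,
        theta_rad = theta_ev, Fb = Fb_ev, K_MPa_sqrt_m = K_ev,
        lefm_valid = val$valid, rp_over_t = val$ratio,
        row.names = NULL
      ),
      sigma_y = sigma_y
    ),
    class = "toughness_result"
  )
}

#' @export
print.toughness_result <- function(x, ...) {
  cat("<toughness_result>\n")
  cat(sprintf("  K_init = %.3f, K_pl = %.3f, K_inst = %.3f MPa*sqrt(m)\n",
              x$K_init, x$K_pl, x$K_inst))
  if (!all(x$events$lefm_valid)) {
    cat("  note: LEFM small-scale-yielding assumption violated at ",
        paste(x$events$event[!x$events$lefm_valid], collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Irwin plastic-zone radius
#'
#' r_p = (K / sigma_y)^2 / (6 pi) under plane strain (default) or
#' (K / sigma_y)^2 / (2 pi) under plane stress.
#'
#' @param K Stress intensity in MPa*sqrt(m) (vectorized).
#' @param sigma_y Yield strength in MPa.
#' @param condition "plane_strain" (default) or "plane_stress".
#' @return Plastic-zone radius in mm.
#' @examples
#' plastic_zone_radius(3, 160)  # ~0.0187 mm
#' @export
plastic_zone_radius <- function(K, sigma_y,
                                condition = c("plane_strain", "plane_stress")) {
  condition <- match.arg(condition)
  if (any(!is.finite(K)) || any(K < 0)) stop("input error: K must be >= 0")
  if (!is.finite(sigma_y) || sigma_y <= 0) {
    stop("input error: sigma_y must be positive")
  }
  const <- if (condition == "plane_strain") 1 / (6 * pi) else 1 / (2 * pi)
  const * (K / sigma_y)^2 * 1000   # (MPa sqrt(m) / MPa)^2 = m -> mm
}

#' Small-scale-yielding validity of an LEFM toughness value
#'
#' The LEFM measure is flagged valid when the Irwin plastic zone is small
#' relative to the controlling dimension, here the cortical wall thickness:
#' r_p <= cutoff_frac * t (default t/10). The ratio r_p / t is always
#' reported.
#'
#' @param K Stress intensity in MPa*sqrt(m) (vectorized).
#' @param section A [cross_section()].
#' @param sigma_y Yield strength in MPa (default 160).
#' @param cutoff_frac Validity cutoff as a fraction of wall thickness
#'   (default 0.1).
#' @param condition Plastic-zone convention, see [plastic_zone_radius()].
#' @return List with logical `valid` and numeric `ratio` (r_p / t).
#' @export
lefm_validity <- function(K, section, sigma_y = 160, cutoff_frac = 0.1,
                          condition = "plane_strain") {
  stopifnot(inherits(section, "cross_section"))
  rp <- plastic_zone_radius(K, sigma_y, condition)
  ratio <- rp / section$t
  list(valid = ratio <= cutoff_frac, ratio = ratio)
}

#' Global sagittal fracture angle
#'
#' Angle of the fracture path from the root of the pre-notch to the periosteal
#' breakout point, measured against the transverse plane: alpha =
#' atan(|delta long-axis| / |delta transverse|) in degrees, so 0 degrees is a
#' perfectly transverse fracture.
#'
#' @param notch_root,breakout Numeric length-2 points `c(long, transverse)` in
#'   mm, sagittal plane, first coordinate along the bone long axis.
#' @return Fracture angle alpha in degrees, in [0, 90].
#' @examples
#' fracture_angle(c(0, 0), c(0.2, 1.0))  # ~11.3 degrees
#' @export
fracture_angle <- function(notch_root, breakout) {
  if (length(notch_root) != 2L || length(breakout) != 2L ||
      any(!is.finite(notch_root)) || any(!is.finite(breakout))) {
    stop("points must be finite length-2 numerics c(long, transverse)")
  }
  d <- breakout - notch_root
  if (all(abs(d) < .Machine$double.eps^0.5)) {
    stop("undefined angle: notch root and breakout point coincide")
  }
  atan2(abs(d[1]), abs(d[2])) * 180 / pi
}
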