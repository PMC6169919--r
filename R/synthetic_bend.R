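# Forward bend-test generator (inverse of the toughness chain) and raster
# section generator with closed-form ground truth.

#' Generate a synchronized bend-test record from a planted R-curve
#'
#' Forward model inverting the toughness chain: a monotone crack-extension
#' series is laid through the planted event extensions, the crack-growth
#' resistance K_R is interpolated linearly in extension between the planted
#' event values, and at every imaging frame the load is solved (exactly, K
#' being linear in load) so that the stress intensity at that frame's crack
#' angle equals K_R. Before initiation the load ramps linearly; after the
#' planted instability frame the load collapses, producing the catastrophic
#' between-frame drop the event detector keys on. The load trace is sampled
#' on a grid that contains every frame timestamp, so with zero load noise
#' [toughness_triplet()] recovers the planted triplet to numerical precision.
#'
#' @param section A [cross_section()].
#' @param notch A [notch_geometry()].
#' @param planted_K Planted K at initiation, peak load and instability, in
#'   MPa sqrt(m), with K at peak the largest load point by construction.
#' @param planted_delta_a Projected crack extension (mm) at the three events;
#'   non-decreasing. The first value must exceed the detection threshold.
#' @param event_times Times (s) of the three events (default 6, 15, 22).
#' @param span Support span in mm (default 8).
#' @param pixel_size Image resolution in um/px (default 2.2).
#' @param frame_rate Imaging frequency in Hz (default 5).
#' @param load_oversample Load samples per imaging frame (default 5).
#' @param load_noise_sd Additive Gaussian load noise SD in N (default 0).
#' @param seed Optional seed for the load noise.
#' @return A [bend_test_record()] with attribute `truth`: planted event frame
#'   indices, K values, crack extensions and event loads.
#' @export
gen_bend_test <- function(section, notch,
                          planted_K = c(2.5, 4.5, 5.5),
                          planted_delta_a = c(0.015, 0.25, 0.55),
                          event_times = c(6, 15, 22),
                          span = 8, pixel_size = 2.2, frame_rate = 5,
                          load_oversample = 5, load_noise_sd = 0,
                          seed = NULL) {
  stopifnot(inherits(section, "cross_section"), inherits(notch, "notch_geometry"))
  if (length(planted_K) != 3 || length(planted_delta_a) != 3 ||
      length(event_times) != 3) {
    stop("planted_K, planted_delta_a and event_times must have length 3")
  }
  if (any(planted_K <= 0)) stop("planted K values must be > 0")
  if (any(diff(planted_delta_a) < 0) || planted_delta_a[1] <= 0) {
    stop("planted_delta_a must be positive and non-decreasing")
  }
  if (any(diff(event_times) <= 0) || event_times[1] <= 0) {
    stop("event_times must be positive and increasing")
  }

  dt <- 1 / frame_rate
  n_post <- 2L
  frame_time <- seq(0, event_times[3] + n_post * dt, by = dt)
  ev <- vapply(event_times, function(tt) which.min(abs(frame_time - tt)), 1L)
  if (ev[1] <= 1 || any(diff(ev) <= 0)) stop("event times too close for the frame clock")
  nf <- length(frame_time)

  # crack-extension series: zero before initiation, piecewise linear through
  # the planted event extensions, then rapid growth after instability
  delta_a <- numeric(nf)
  delta_a[ev[1]:ev[2]] <- seq(planted_delta_a[1], planted_delta_a[2],
                              length.out = ev[2] - ev[1] + 1)
  delta_a[ev[2]:ev[3]] <- seq(planted_delta_a[2], planted_delta_a[3],
                              length.out = ev[3] - ev[2] + 1)
  if (nf > ev[3]) {
    delta_a[(ev[3] + 1):nf] <- planted_delta_a[3] + 0.3 * seq_len(nf - ev[3])
  }

  # load per frame solved from the planted R-curve (K linear in load)
  load_for_K <- function(K, da) {
    theta <- half_crack_angle(notch, da, section)
    k_unit <- tryCatch(
      stress_intensity(1, span, section, theta),
      error = function(e) stop("unreachable planted K: ", conditionMessage(e)))
    K / k_unit
  }
  frame_load <- numeric(nf)
  cracked <- ev[1]:ev[3]
  K_R <- stats::approx(planted_delta_a, planted_K, xout = delta_a[cracked])$y
  frame_load[cracked] <- load_for_K(K_R, delta_a[cracked])
  frame_load[1:ev[1]] <- frame_load[ev[1]] * (seq_len(ev[1]) - 1) / (ev[1] - 1)
  if (nf > ev[3]) {
    frame_load[(ev[3] + 1):nf] <- frame_load[ev[3]] * c(0.3, 0.05)[seq_len(nf - ev[3])]
  }
  if (which.max(frame_load) != ev[2]) {
    stop("inconsistent planted R-curve: peak load does not fall on the peak event")
  }

  # denser load trace containing every frame timestamp exactly
  time <- seq(0, max(frame_time), by = dt / load_oversample)
  load <- stats::approx(frame_time, frame_load, xout = time)$y
  if (load_noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    load <- pmax(load + stats::rnorm(length(load), 0, load_noise_sd), 0)
  }
  displacement <- 0.1 / 60 * time   # 0.1 mm/min crosshead proxy

  rec <- bend_test_record(time, load, displacement, frame_time, delta_a,
                          span = span, pixel_size = pixel_size)
  attr(rec, "truth") <- list(
    event_frames = as.integer(ev), K = planted_K,
    delta_a = planted_delta_a, load = frame_load[ev])
  rec
}

#' Generate a raster density section with closed-form ground truth
#'
#' Rasterizes an (optionally elliptical) annulus at a planted density on a
#' zero background, by pixel-centre inclusion. `ellipticity` q scales the
#' semi-axes area-preservingly (a = R sqrt(q), b = R / sqrt(q)); with
#' `wall = "offset"` the endosteal boundary is instead the inward offset of
#' the periosteal ellipse at constant distance R_o - R_i, giving a constant
#' wall. The attached sidecar holds the continuous closed forms (areas,
#' principal moments, wall thickness) used as oracles.
#'
#' @param R_o,R_i Outer and inner radii in mm, R_o > R_i > 0.
#' @param ellipticity Axis ratio q >= 1 (1 = circle).
#' @param pixel_size Pixel size in um (default 12).
#' @param density Planted bone density in mg HA/cm^3 (default 1200).
#' @param noise_sd Additive Gaussian density noise SD (default 0).
#' @param wall "ellipse" (confocal scaled ellipses) or "offset" (constant
#'   wall thickness R_o - R_i).
#' @param margin Background margin around the section in mm (default 0.2).
#' @param seed Optional seed for the density noise.
#' @return A [section_image()] with attribute `truth` (list: mask, Tt.Ar,
#'   Ct.Ar, Es.Ar in mm^2, I_min/I_max in mm^4 or NA for offset walls,
#'   Ct.Th in mm, TMD).
#' @export
gen_section_mask <- function(R_o = 1.0, R_i = 0.6, ellipticity = 1,
                             pixel_size = 12, density = 1200, noise_sd = 0,
                             wall = c("ellipse", "offset"), margin = 0.2,
                             seed = NULL) {
  wall <- match.arg(wall)
  if (R_o <= R_i || R_i <= 0) stop("invalid radii: need R_o > R_i > 0")
  if (ellipticity < 1) stop("ellipticity must be >= 1")
  px <- pixel_size / 1000
  q <- sqrt(ellipticity)
  a_o <- R_o * q; b_o <- R_o / q
  half <- a_o + margin
  n <- 2L * ceiling(half / px) + 1L
  ctr <- (n + 1) / 2
  xs <- (seq_len(n) - ctr) * px
  X <- matrix(xs, n, n)
  Y <- matrix(xs, n, n, byrow = TRUE)
  outer_mask <- (X / a_o)^2 + (Y / b_o)^2 <= 1

  if (wall == "ellipse") {
    a_i <- R_i * q; b_i <- R_i / q
    mask <- outer_mask & ((X / a_i)^2 + (Y / b_i)^2 > 1)
    truth <- list(
      Tt.Ar = pi * a_o * b_o,
      Ct.Ar = pi * (a_o * b_o - a_i * b_i),
      Es.Ar = pi * a_i * b_i,
      I_x = pi / 4 * (a_o * b_o^3 - a_i * b_i^3),
      I_y = pi / 4 * (a_o^3 * b_o - a_i^3 * b_i),
      Ct.Th = if (ellipticity == 1) R_o - R_i else NA_real_
    )
    truth$I_min <- min(truth$I_x, truth$I_y)
    truth$I_max <- max(truth$I_x, truth$I_y)
  } else {
    t_wall <- R_o - R_i
    dtr <- EBImage::distmap(matrix(as.numeric(outer_mask), n, n))@.Data
    mask <- outer_mask & (dtr * px <= t_wall)
    truth <- list(
      Tt.Ar = pi * a_o * b_o, Ct.Ar = NA_real_, Es.Ar = NA_real_,
      I_min = NA_real_, I_max = NA_real_, Ct.Th = t_wall
    )
  }
  if (!any(mask)) stop("degenerate raster: empty section mask")

  grid <- matrix(0, n, n)
  grid[mask] <- density
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    grid <- pmax(grid + matrix(stats::rnorm(n * n, 0, noise_sd), n, n), 0)
  }
  img <- section_image(grid, pixel_size)
  truth$mask <- matrix(as.integer(mask), n, n)
  truth$TMD <- density
  attr(img, "truth") <- truth
  img
}
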