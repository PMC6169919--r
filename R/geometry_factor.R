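# Geometry factor for a circumferential through-wall crack in a cylinder
# loaded in bending, in the Takahashi/Zahoor polynomial form
#
#   F_b(theta, rho) = 1 + A(rho) * (4.5967 * (theta/pi)^1.5
#                                   + 2.6422 * (theta/pi)^4.24)
#
# with rho = R_m/t. A(rho) is tabulated below and linearly interpolated
# between tabulated ratios. The published branches
#   A = (0.125 rho - 0.25)^0.25   (5 <= rho <= 10)
#   A = (0.4   rho - 3.0)^0.25    (10 <= rho <= 20)
# are extended down to rho = 2.5 with the low branch so that thick-walled
# rodent diaphyses (rho ~ 3-4) are covered; the extension is part of the
# versioned table, not recomputed at run time.
#
# Table version: v1.

.fb_table <- data.frame(
  ratio = c(2.5, 3, 4, 5, 7.5, 10, 15, 20),
  A = c(0.50000000, 0.59460356, 0.70710678, 0.78254229,
        0.91058014, 1.00000000, 1.31607401, 1.49534878)
)

.fb_theta_max <- 0.6 * pi
.fb_c1 <- 4.5967
.fb_c2 <- 2.6422
.fb_e1 <- 1.5
.fb_e2 <- 4.24

#' Geometry factor for a through-wall circumferential crack under bending
#'
#' Dimensionless boundary-correction factor F_b entering
#' K = F_b * sigma_b * sqrt(pi * R_m * theta). Tabulated by R_m/t and
#' interpolated linearly between tabulated ratios; polynomial in theta/pi.
#' F_b is 1 in the vanishing-crack limit and increases monotonically with
#' crack angle.
#'
#' @param theta Half crack angle in radians; supported on (0, 0.6*pi].
#' @param ratio Radius-to-thickness ratio R_m/t; supported on [2.5, 20].
#' @return Dimensionless factor >= 1, vectorized over `theta`.
#' @examples
#' geometry_factor(0.5, 4)
#' @export
geometry_factor <- function(theta, ratio) {
  if (!is.numeric(theta) || !is.numeric(ratio) || length(ratio) != 1L) {
    stop("theta must be numeric and ratio a single number")
  }
  if (any(!is.finite(theta)) || !is.finite(ratio)) {
    stop("input error: non-finite arguments")
  }
  rng <- range(.fb_table$ratio)
  if (ratio < rng[1] || ratio > rng[2]) {
    stop(sprintf(
      "range error: R_m/t = %.3g outside the supported window [%.1f, %.1f]",
      ratio, rng[1], rng[2]))
  }
  if (any(theta <= 0) || any(theta > .fb_theta_max)) {
    stop(sprintf(
      "range error: theta outside the supported window (0, %.4f] rad",
      .fb_theta_max))
  }
  A <- stats::approx(.fb_table$ratio, .fb_table$A, xout = ratio)$y
  u <- theta / pi
  1 + A * (.fb_c1 * u^.fb_e1 + .fb_c2 * u^.fb_e2)
}

#' Tabulated geometry-factor coefficients
#'
#' Returns the versioned coefficient table behind [geometry_factor()]:
#' one amplitude `A` per tabulated R_m/t, applied to the fixed polynomial
#' `4.5967 (theta/pi)^1.5 + 2.6422 (theta/pi)^4.24`.
#'
#' @return data.frame with columns `ratio` and `A`.
#' @export
geometry_factor_table <- function() .fb_table
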