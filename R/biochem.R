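# Plate-reader biochemistry: quinine-sulfate standard curves, hydroxyproline
# derived collagen, AGE normalization, mineral-to-matrix ratio.

#' Fit a fluorescence standard curve
#'
#' Ordinary least squares of fluorescence on concentration, as used for the
#' quinine sulfate pentosidine standards. At least three standards are
#' required and the fitted slope must be positive.
#'
#' @param concentration Standard concentrations (e.g. ug quinine sulfate).
#' @param fluorescence Measured fluorescence (arbitrary units).
#' @return Object of class `standard_curve` with `slope`, `intercept`,
#'   `r_squared`, the standards, and the underlying `lm` fit.
#' @export
fit_standard_curve <- function(concentration, fluorescence) {
  if (length(concentration) != length(fluorescence)) {
    stop("concentration and fluorescence must have equal length")
  }
  if (length(unique(concentration)) < 3) {
    stop("calibration error: need standards at >= 3 concentrations")
  }
  if (any(fluorescence < 0)) stop("input error: negative fluorescence")
  fit <- stats::lm(fluorescence ~ concentration)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) {
    stop("calibration error: non-monotone standards (slope <= 0)")
  }
  ss_tot <- sum((fluorescence - mean(fluorescence))^2)
  r2 <- 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         concentration = concentration, fluorescence = fluorescence,
         fit = fit),
    class = "standard_curve"
  )
}

#' Inverse prediction from a standard curve
#'
#' Converts sample fluorescence to concentration via the fitted line.
#' Predictions beyond 120 percent of the top standard are refused (returned as
#' NA with a warning) rather than extrapolated.
#'
#' @param curve A [fit_standard_curve()] result.
#' @param fluorescence Sample fluorescence values.
#' @return Concentrations on the standards' scale.
#' @export
predict_concentration <- function(curve, fluorescence) {
  stopifnot(inherits(curve, "standard_curve"))
  conc <- (fluorescence - curve$intercept) / curve$slope
  top <- 1.2 * max(curve$concentration)
  out <- conc > top
  if (any(out)) {
    warning(sprintf(
      "%d reading(s) beyond 120%% of the top standard; not extrapolated",
      sum(out)))
    conc[out] <- NA_real_
  }
  conc
}

#' Collagen mass from hydroxyproline
#'
#' Collagen is assumed to be 13.5 percent hydroxyproline by mass.
#'
#' @param hyp_mass Hydroxyproline mass in ug (vectorized).
#' @param fraction Hydroxyproline mass fraction of collagen (default 0.135).
#' @return Collagen mass in ug.
#' @examples
#' collagen_from_hydroxyproline(13.5)  # 100
#' @export
collagen_from_hydroxyproline <- function(hyp_mass, fraction = 0.135) {
  if (any(!is.finite(hyp_mass)) || any(hyp_mass < 0)) {
    stop("input error: hydroxyproline mass must be >= 0")
  }
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  hyp_mass / fraction
}

#' Reduce technical replicates with a CV quality flag
#'
#' @param readings Replicate readings (>= 1).
#' @param cv_limit Replicate coefficient-of-variation limit (default 0.15).
#' @return List with `mean`, `cv`, `n`, logical `flag` (CV above limit) and
#'   `note` ("no-replicate" for single readings).
#' @export
replicate_reduce <- function(readings, cv_limit = 0.15) {
  if (length(readings) < 1 || any(!is.finite(readings))) {
    stop("input error: need at least one finite reading")
  }
  m <- mean(readings)
  if (length(readings) == 1L) {
    return(list(mean = m, cv = NA_real_, n = 1L, flag = FALSE,
                note = "no-replicate"))
  }
  cv <- stats::sd(readings) / m
  list(mean = m, cv = cv, n = length(readings), flag = cv > cv_limit,
       note = NA_character_)
}

#' Normalize an AGE measurement to collagen content
#'
#' @param analyte_amount Analyte amount (ug quinine-sulfate equivalents for
#'   pentosidine, fluorescence units for nsAGE).
#' @param collagen Collagen mass in ug, > 0.
#' @return Analyte per ug collagen.
#' @export
normalize_age <- function(analyte_amount, collagen) {
  if (any(!is.finite(collagen)) || any(collagen <= 0)) {
    stop("normalization error: collagen mass must be > 0")
  }
  if (any(analyte_amount < 0)) stop("input error: negative analyte amount")
  analyte_amount / collagen
}

#' Mineral-to-matrix ratio
#'
#' Ratio of micro-CT-derived bone mineral content to assay-derived collagen
#' content.
#'
#' @param bone_mineral_content Bone mineral content in ug.
#' @param collagen Collagen mass in ug, > 0.
#' @return Dimensionless ratio.
#' @export
mineral_to_matrix <- function(bone_mineral_content, collagen) {
  if (any(!is.finite(collagen)) || any(collagen <= 0)) {
    stop("normalization error: collagen mass must be > 0")
  }
  if (any(bone_mineral_content < 0)) stop("input error: negative mineral content")
  bone_mineral_content / collagen
}
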