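# Study calibration: planted means, spreads and effects for the synthetic
# data generators. The default calibration ships as a versioned YAML file.

#' Load a study calibration
#'
#' Reads the YAML calibration that drives the synthetic-data generators. With
#' no argument, the packaged default calibration is returned; it anchors the
#' Sham instability toughness at 5.5 MPa sqrt(m) with COV 0.14 and plants the
#' study's reported percent changes, regression slopes and R-squared values.
#' Anchors the study did not report are marked `source: assumed` in the file.
#'
#' @param path Optional path to a calibration YAML file.
#' @return Object of class `study_calibration` (a named list).
#' @export
study_calibration <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_calibration.yaml",
                        package = "femurtough")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("calibration file not found: ", path)
  }
  cal <- yaml::read_yaml(path)
  validate_calibration(cal)
  structure(cal, class = "study_calibration")
}

#' Validate a calibration list
#'
#' Checks the structural invariants of a calibration: positive COVs and
#' multipliers, per-week vectors aligned with the week design, planted
#' R-squared values inside (0, 1).
#'
#' @param cal Calibration list.
#' @return The calibration, invisibly; errors on violation.
#' @export
validate_calibration <- function(cal) {
  if (is.null(cal$cohort) || is.null(cal$cohort$weeks)) {
    stop("invalid calibration: missing cohort design")
  }
  nw <- length(cal$cohort$weeks)
  for (nm in names(cal$cohort$outcomes)) {
    oc <- cal$cohort$outcomes[[nm]]
    if (length(oc$sham_mean) != nw || length(oc$rtx_multiplier) != nw) {
      stop("invalid calibration: per-week vectors misaligned for ", nm)
    }
    if (oc$cov <= 0) stop("invalid calibration: COV must be > 0 for ", nm)
    if (any(oc$rtx_multiplier <= 0)) {
      stop("invalid calibration: multipliers must be > 0 for ", nm)
    }
  }
  for (nm in names(cal$paired$outcomes)) {
    oc <- cal$paired$outcomes[[nm]]
    if (oc$cov <= 0 || oc$multiplier <= 0 || oc$control_mean <= 0) {
      stop("invalid calibration: paired parameters must be > 0 for ", nm)
    }
  }
  if (!is.null(cal$paired) &&
      (cal$paired$correlation <= 0 || cal$paired$correlation >= 1)) {
    stop("invalid calibration: paired correlation must lie in (0, 1)")
  }
  for (nm in names(cal$ribosylation$outcomes)) {
    oc <- cal$ribosylation$outcomes[[nm]]
    if (oc$r_squared <= 0 || oc$r_squared >= 1) {
      stop("invalid calibration: planted R^2 must lie in (0, 1) for ", nm)
    }
  }
  invisible(cal)
}

#' @export
print.study_calibration <- function(x, ...) {
  cat(sprintf(
    "<study_calibration> v%s: %d cohort outcomes x %d weeks (n = %d/cell), %d paired outcomes, %d ribosylation outcomes\n",
    x$version, length(x$cohort$outcomes), length(x$cohort$weeks),
    x$cohort$n_per_cell, length(x$paired$outcomes),
    length(x$ribosylation$outcomes)))
  invisible(x)
}
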