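# Synthetic study generators: longitudinal cohort, paired devitalized femurs,
# ribosylation dose-response, and the fractionation dose model. Each returns
# a long-format cohort table with the planted ground truth attached as the
# "truth" attribute.

.norm_cell <- function(n, mean, cov) stats::rnorm(n, mean, cov * mean)

#' Generate a longitudinal two-group cohort with planted effects
#'
#' Draws normal outcomes per group x week cell with the calibration's planted
#' means (Sham anchor, RTx multiplier) and COV-parameterized spread. The
#' default design mirrors the emulated study: Sham and RTx at 0, 4, 8, 12
#' weeks, n = 15 femurs per cell.
#'
#' @param calibration A [study_calibration()].
#' @param seed Integer seed; identical seeds give identical tables.
#' @param n Per-cell sample size (default from the calibration).
#' @param outcomes Outcome names to generate (default: all calibrated).
#' @return Long-format data.frame (specimen, group, time, outcome, value) with
#'   attribute `truth`: planted cell means and percent changes.
#' @export
gen_cohort <- function(calibration, seed, n = NULL, outcomes = NULL) {
  stopifnot(inherits(calibration, "study_calibration"))
  co <- calibration$cohort
  if (is.null(n)) n <- co$n_per_cell
  if (is.null(outcomes)) outcomes <- names(co$outcomes)
  miss <- setdiff(outcomes, names(co$outcomes))
  if (length(miss) > 0) stop("uncalibrated outcomes: ", paste(miss, collapse = ", "))
  set.seed(seed)
  rows <- list(); truth <- list()
  for (oc in outcomes) {
    cfg <- co$outcomes[[oc]]
    for (w in seq_along(co$weeks)) {
      mu_s <- cfg$sham_mean[w]
      mu_r <- mu_s * cfg$rtx_multiplier[w]
      wk <- co$weeks[w]
      rows[[length(rows) + 1L]] <- data.frame(
        specimen = sprintf("S%s_w%s_%02d", "Sham", wk, seq_len(n)),
        group = "Sham", time = wk, outcome = oc,
        value = .norm_cell(n, mu_s, cfg$cov))
      rows[[length(rows) + 1L]] <- data.frame(
        specimen = sprintf("S%s_w%s_%02d", "RTx", wk, seq_len(n)),
        group = "RTx", time = wk, outcome = oc,
        value = .norm_cell(n, mu_r, cfg$cov))
      truth[[length(truth) + 1L]] <- data.frame(
        outcome = oc, time = wk, sham_mean = mu_s, rtx_mean = mu_r,
        cov = cfg$cov, pct_change = (mu_r / mu_s - 1) * 100)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- do.call(rbind, truth)
  attr(out, "seed") <- seed
  out
}

#' Generate a paired devitalized-femur experiment
#'
#' Emulates the unilateral-irradiation design: each animal contributes a
#' control and a treated femur. A shared per-animal baseline carries the
#' between-animal variance (fraction `correlation` of the total), the treated
#' femur is the baseline times the planted multiplier, and femur-level noise
#' carries the rest, so the planted within-pair correlation is the
#' calibration's `correlation`.
#'
#' @param calibration A [study_calibration()].
#' @param seed Integer seed.
#' @param n Number of pairs (default from the calibration).
#' @param outcomes Outcome names (default: all paired-calibrated).
#' @return Long-format data.frame with groups "control" and "RTx"; `specimen`
#'   identifies the animal. Attribute `truth` holds planted means and the
#'   paired percent change.
#' @export
gen_paired_femurs <- function(calibration, seed, n = NULL, outcomes = NULL) {
  stopifnot(inherits(calibration, "study_calibration"))
  pa <- calibration$paired
  if (is.null(n)) n <- pa$n_pairs
  if (is.null(outcomes)) outcomes <- names(pa$outcomes)
  rho <- pa$correlation
  set.seed(seed)
  rows <- list(); truth <- list()
  for (oc in outcomes) {
    cfg <- pa$outcomes[[oc]]
    sigma <- cfg$cov * cfg$control_mean
    base <- stats::rnorm(n, cfg$control_mean, sqrt(rho) * sigma)
    ctrl <- base + stats::rnorm(n, 0, sqrt(1 - rho) * sigma)
    trt <- base * cfg$multiplier +
      stats::rnorm(n, 0, sqrt(1 - rho) * sigma * cfg$multiplier)
    id <- sprintf("A%02d", seq_len(n))
    rows[[length(rows) + 1L]] <- data.frame(
      specimen = rep(id, 2), group = rep(c("control", "RTx"), each = n),
      time = 0, outcome = oc, value = c(ctrl, trt))
    truth[[length(truth) + 1L]] <- data.frame(
      outcome = oc, control_mean = cfg$control_mean,
      rtx_mean = cfg$control_mean * cfg$multiplier,
      pct_change = (cfg$multiplier - 1) * 100, correlation = rho)
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- do.call(rbind, truth)
  attr(out, "seed") <- seed
  out
}

#' Generate the ex vivo ribosylation dose-response experiment
#'
#' Outcomes follow value = intercept + slope * day + residual, with the
#' residual SD derived from the planted R-squared and the balanced day
#' design's variance: sigma^2 = slope^2 * var(day) * (1/R^2 - 1). For the
#' default days 0/3/7/14 the (population) design variance is 27.5 day^2.
#'
#' @param calibration A [study_calibration()].
#' @param seed Integer seed.
#' @param n Femurs per day group (default from the calibration).
#' @param outcomes Outcome names (default: all ribosylation-calibrated).
#' @return Long-format data.frame with `time` holding the incubation day and
#'   group "ribose"; attribute `truth` holds planted slopes, intercepts,
#'   R-squared and residual SD.
#' @export
gen_ribosylation <- function(calibration, seed, n = NULL, outcomes = NULL) {
  stopifnot(inherits(calibration, "study_calibration"))
  ri <- calibration$ribosylation
  if (is.null(n)) n <- ri$n_per_day
  if (is.null(outcomes)) outcomes <- names(ri$outcomes)
  days <- ri$days
  var_day <- mean(days^2) - mean(days)^2
  set.seed(seed)
  rows <- list(); truth <- list()
  for (oc in outcomes) {
    cfg <- ri$outcomes[[oc]]
    sigma <- abs(cfg$slope) * sqrt(var_day * (1 / cfg$r_squared - 1))
    for (d in days) {
      mu <- cfg$intercept + cfg$slope * d
      rows[[length(rows) + 1L]] <- data.frame(
        specimen = sprintf("R_d%02d_%02d", d, seq_len(n)),
        group = "ribose", time = d, outcome = oc,
        value = mu + stats::rnorm(n, 0, sigma))
    }
    truth[[length(truth) + 1L]] <- data.frame(
      outcome = oc, intercept = cfg$intercept, slope = cfg$slope,
      r_squared = cfg$r_squared, resid_sd = sigma)
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- do.call(rbind, truth)
  attr(out, "seed") <- seed
  out
}

#' Biologically effective dose under the linear-quadratic model
#'
#' BED = n * d * (1 + d / (alpha/beta)) for n fractions of d Gy. For the
#' emulated protocol (4 daily fractions of 5 Gy, alpha/beta = 2.8 Gy) this is
#' 55.7 Gy.
#'
#' @param n_fractions Number of fractions, > 0.
#' @param dose_per_fraction Dose per fraction in Gy, > 0.
#' @param alpha_beta Tissue alpha/beta ratio in Gy, > 0.
#' @return Biologically effective dose in Gy.
#' @examples
#' bed_linear_quadratic(4, 5, 2.8)
#' @export
bed_linear_quadratic <- function(n_fractions, dose_per_fraction, alpha_beta) {
  if (!all(is.finite(c(n_fractions, dose_per_fraction, alpha_beta)))) {
    stop("input error: non-finite arguments")
  }
  if (alpha_beta <= 0) stop("input error: alpha/beta must be > 0")
  if (n_fractions <= 0 || dose_per_fraction < 0) {
    stop("input error: fractions and dose must be positive")
  }
  n_fractions * dose_per_fraction * (1 + dose_per_fraction / alpha_beta)
}
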