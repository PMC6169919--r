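# Statistical battery for the longitudinal study: per-time-point t tests,
# ANCOVA with treatment-by-time interaction, ANOVA + Tukey, regressions,
# Cohen's d, percent change. Cohort data travel as long-format data frames
# with columns specimen, group, time, outcome, value.

.check_cohort <- function(table) {
  need <- c("specimen", "group", "time", "outcome", "value")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0) {
    stop("cohort table missing columns: ", paste(miss, collapse = ", "))
  }
  invisible(table)
}

#' Signed percent change of a treated mean relative to a reference mean
#'
#' Computed as (treated - reference) / reference * 100.
#'
#' @param treated_mean,reference_mean Group means; reference must be nonzero.
#' @return Percent change.
#' @examples
#' percent_change(3.19, 5.5)  # -42
#' @export
percent_change <- function(treated_mean, reference_mean) {
  if (any(reference_mean == 0)) stop("reference mean must be nonzero")
  (treated_mean - reference_mean) / reference_mean * 100
}

#' Per-time-point two-sample comparisons of one outcome
#'
#' Unpaired Student's t test (equal variances by default; set `welch = TRUE`
#' for the Welch form) of treated vs reference group at every time point, with
#' descriptives and the percent change of group means. No multiplicity
#' correction is applied across time points.
#'
#' @param table Long-format cohort data frame.
#' @param outcome Outcome name to analyze.
#' @param reference,treated Group labels (defaults "Sham" and "RTx").
#' @param welch Use the Welch unequal-variance t test (default FALSE).
#' @return data.frame with one row per time point: group means and SDs, n,
#'   percent change, t statistic, p value and a significance star at p < 0.05.
#' @export
timepoint_tests <- function(table, outcome, reference = "Sham",
                            treated = "RTx", welch = FALSE) {
  .check_cohort(table)
  d <- table[table$outcome == outcome & table$group %in% c(reference, treated), ]
  if (nrow(d) == 0) stop("outcome not present: ", outcome)
  out <- lapply(sort(unique(d$time)), function(tp) {
    ref <- d$value[d$time == tp & d$group == reference]
    trt <- d$value[d$time == tp & d$group == treated]
    if (length(ref) < 2 || length(trt) < 2) {
      stop(sprintf("need n >= 2 in both groups at time %s", tp))
    }
    tt <- stats::t.test(trt, ref, var.equal = !welch)
    data.frame(
      time = tp, n_ref = length(ref), n_trt = length(trt),
      mean_ref = mean(ref), sd_ref = stats::sd(ref),
      mean_trt = mean(trt), sd_trt = stats::sd(trt),
      pct_change = percent_change(mean(trt), mean(ref)),
      t = unname(tt$statistic), p = tt$p.value,
      signif = tt$p.value < 0.05
    )
  })
  do.call(rbind, out)
}

#' Paired comparison for the contralateral-control design
#'
#' Two-sided paired Student's t test of treated vs control femur within
#' animal.
#'
#' @param table Long-format cohort data frame; `specimen` identifies the
#'   animal, `group` the arm.
#' @param outcome Outcome name.
#' @param reference,treated Arm labels (defaults "control" and "RTx").
#' @return List with `mean_diff`, `pct_change` (on arm means), `t`, `p`, `n`.
#' @export
paired_tests <- function(table, outcome, reference = "control",
                         treated = "RTx") {
  .check_cohort(table)
  d <- table[table$outcome == outcome, ]
  ref <- d[d$group == reference, c("specimen", "value")]
  trt <- d[d$group == treated, c("specimen", "value")]
  m <- merge(ref, trt, by = "specimen", suffixes = c("_ref", "_trt"))
  if (nrow(m) < nrow(ref) || nrow(m) < nrow(trt)) {
    stop("broken pairs: every specimen needs both arms")
  }
  if (nrow(m) < 2) stop("need at least two complete pairs")
  tt <- stats::t.test(m$value_trt, m$value_ref, paired = TRUE)
  list(mean_diff = mean(m$value_trt - m$value_ref),
       pct_change = percent_change(mean(m$value_trt), mean(m$value_ref)),
       t = unname(tt$statistic), p = tt$p.value, n = nrow(m))
}

#' ANCOVA of one outcome on treatment with time as covariate
#'
#' Fits value ~ group * time and reports the effect p values for treatment,
#' time and the treatment-by-time interaction (car type-II tests, which match
#' JMP-style effect tests on this balanced design) plus the full-model R
#' squared. The common time slope from the additive model value ~ group +
#' time is reported alongside; by the study's convention it is the quantity
#' of interest when the interaction is not significant.
#'
#' @param table Long-format cohort data frame.
#' @param outcome Outcome name.
#' @param reference Reference group label used for coding (default "Sham").
#' @return Object of class `ancova_result`: `p_treatment`, `p_time`,
#'   `p_interaction`, `r_squared`, `common_slope` (outcome units per week),
#'   and the two fitted models.
#' @export
ancova <- function(table, outcome, reference = "Sham") {
  .check_cohort(table)
  d <- table[table$outcome == outcome, ]
  if (length(unique(d$time)) < 2) stop("need >= 2 time points")
  d$group <- stats::relevel(factor(d$group), ref = reference)
  full <- stats::lm(value ~ group * time, data = d)
  if (any(!is.finite(stats::coef(full)))) stop("rank-deficient design")
  s_full <- suppressWarnings(summary(full))  # exact fits trip a benign warning
  if (s_full$sigma < 1e-10) {
    # exact (noiseless) fit: effect tests are degenerate
    p <- c(group = NA_real_, time = NA_real_, `group:time` = NA_real_)
  } else {
    eff <- car::Anova(full, type = 2)
    p <- eff[["Pr(>F)"]]
    names(p) <- rownames(eff)
  }
  additive <- stats::lm(value ~ group + time, data = d)
  structure(
    list(p_treatment = unname(p["group"]), p_time = unname(p["time"]),
         p_interaction = unname(p["group:time"]),
         r_squared = s_full$r.squared,
         common_slope = unname(stats::coef(additive)["time"]),
         model = full, additive_model = additive),
    class = "ancova_result"
  )
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf(
    "<ancova_result> p(treatment) = %.3g, p(time) = %.3g, p(interaction) = %.3g, R^2 = %.2f\n",
    x$p_treatment, x$p_time, x$p_interaction, x$r_squared))
  cat(sprintf("  common time slope (additive model): %.4f per week\n",
              x$common_slope))
  invisible(x)
}

#' One-way ANOVA with Tukey HSD post-hoc tests
#'
#' @param values Numeric outcome vector.
#' @param groups Group labels (>= 3 groups).
#' @return List with `p_omnibus` and `tukey`, a data.frame of pairwise
#'   comparisons (difference, adjusted p).
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 3) stop("need >= 3 groups")
  fit <- stats::aov(values ~ groups)
  p_omni <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$groups
  list(
    p_omnibus = p_omni,
    tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                       p_adj = tk[, "p adj"], row.names = NULL)
  )
}

#' Simple linear regression with slope test
#'
#' @param x,y Numeric vectors, >= 3 points, var(x) > 0.
#' @return List with `slope`, `intercept`, `r_squared`, `p` (two-sided slope
#'   test) and the `lm` fit.
#' @export
linfit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stop("need >= 3 (x, y) points")
  if (stats::var(x) == 0) stop("degenerate x: no variance")
  fit <- stats::lm(y ~ x)
  s <- suppressWarnings(summary(fit))   # exact fits trip a benign warning
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared, p = s$coefficients[2, 4], fit = fit)
}

#' Cohen's d standardized mean difference
#'
#' d = (mean_a - mean_b) / pooled SD, with the conventional size classes at
#' |d| >= 0.2 (small), 0.5 (medium), 0.8 (large).
#'
#' @param group_a,group_b Numeric vectors, n >= 2 each.
#' @return List with `d` and `size_class`.
#' @export
cohens_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("need n >= 2 in each group")
  sp <- sqrt(((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
               (na + nb - 2))
  if (sp == 0) stop("zero pooled SD: d undefined")
  d <- (mean(group_a) - mean(group_b)) / sp
  cls <- if (abs(d) >= 0.8) "large" else if (abs(d) >= 0.5) "medium"
         else if (abs(d) >= 0.2) "small" else "negligible"
  list(d = d, size_class = cls)
}
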