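#' Effect-measure algebra on the analysis scale
#'
#' Ratio measures (odds ratio, risk ratio, hazard ratio) are analysed on the
#' natural-log scale; mean differences on the identity scale.  These helpers
#' convert among a point estimate, its confidence interval, its standard
#' error and its two-sided Wald P-value, so that a trial result reported in
#' any one of those forms can be resolved to the triplet (theta, SE, P)
#' needed downstream.
#'
#' @name effects
NULL

.ratio_measures <- c("OR", "RR", "HR")

#' Construct an intervention-effect estimate
#'
#' Bundles a published effect estimate with whatever precision information
#' accompanies it (confidence interval, standard error on the analysis
#' scale, or a two-sided P-value).  At least one of the three must be
#' supplied.  Ratio measures (`"OR"`, `"RR"`, `"HR"`) must have a positive
#' point estimate and are carried on the log scale; mean differences
#' (`"MD"`) stay on the identity scale.
#'
#' @param measure one of `"OR"`, `"RR"`, `"HR"`, `"MD"`.
#' @param point point estimate on the measure's own scale (ratio scale for
#'   OR/RR/HR, outcome units for MD).  May be omitted when `log_estimate`
#'   is given for a ratio measure.
#' @param log_estimate optional estimate already on the analysis scale
#'   (log-ratio or mean difference); used verbatim when supplied, e.g. to
#'   reproduce a published "log odds ratio" without re-rounding.
#' @param ci_lower,ci_upper optional confidence limits, same scale as `point`.
#' @param ci_level confidence level in (0, 1); default 0.95.
#' @param se optional standard error on the analysis scale.
#' @param p optional two-sided P-value in (0, 1].
#' @param direction_of_benefit `"less_than_null"` if values below the null
#'   (1 for ratios, 0 for MD) represent benefit, else `"greater_than_null"`.
#' @return an object of class `"effect_estimate"`.
#' @examples
#' effect_estimate("HR", 0.92, ci_lower = 0.86, ci_upper = 0.998, p = 0.04)
#' @export
effect_estimate <- function(measure, point = NULL, log_estimate = NULL,
                            ci_lower = NULL, ci_upper = NULL, ci_level = 0.95,
                            se = NULL, p = NULL,
                            direction_of_benefit = c("less_than_null",
                                                     "greater_than_null")) {
  measure <- match.arg(measure, c(.ratio_measures, "MD"))
  direction_of_benefit <- match.arg(direction_of_benefit)
  if (is.null(point) && is.null(log_estimate))
    stop("supply 'point' or 'log_estimate'", call. = FALSE)
  if (is.null(point)) {
    point <- if (measure %in% .ratio_measures) exp(log_estimate) else log_estimate
  }
  if (measure %in% .ratio_measures && point <= 0)
    stop("ratio estimates must be positive", call. = FALSE)
  has_ci <- !is.null(ci_lower) && !is.null(ci_upper)
  if (has_ci) {
    if (!(ci_lower < point && point < ci_upper))
      stop("confidence interval must bracket the point estimate", call. = FALSE)
    if (ci_level <= 0 || ci_level >= 1)
      stop("'ci_level' must be in (0, 1)", call. = FALSE)
  }
  if (!is.null(se) && se <= 0) stop("'se' must be positive", call. = FALSE)
  if (!is.null(p) && (p <= 0 || p > 1))
    stop("'p' must be in (0, 1]", call. = FALSE)
  if (!has_ci && is.null(se) && is.null(p))
    stop("at least one of CI, 'se' or 'p' is required", call. = FALSE)
  structure(list(measure = measure, point = point,
                 log_estimate = log_estimate,
                 ci_lower = ci_lower, ci_upper = ci_upper, ci_level = ci_level,
                 se = se, p = p,
                 direction_of_benefit = direction_of_benefit),
            class = "effect_estimate")
}

#' Transform an estimate to its analysis scale
#'
#' Natural log for OR/RR/HR, identity for MD.  When the estimate carries an
#' explicit `log_estimate` that value is returned verbatim.
#'
#' @param est an [effect_estimate()] object, or a bare number together with
#'   `measure`.
#' @param measure required when `est` is a bare number.
#' @return an object of class `"analysis_scale_value"` with fields `value`,
#'   `scale` (`"log"` or `"identity"`) and `measure`.
#' @examples
#' to_analysis_scale(0.92, measure = "OR")$value  # -0.0834
#' @export
to_analysis_scale <- function(est, measure = NULL) {
  if (inherits(est, "effect_estimate")) {
    measure <- est$measure
    if (!is.null(est$log_estimate))
      return(structure(list(value = est$log_estimate,
                            scale = analysis_scale_of(measure),
                            measure = measure),
                       class = "analysis_scale_value"))
    est <- est$point
  }
  measure <- match.arg(measure, c(.ratio_measures, "MD"))
  if (measure %in% .ratio_measures) {
    if (est <= 0) stop("ratio estimates must be positive", call. = FALSE)
    value <- log(est)
    scale <- "log"
  } else {
    value <- est
    scale <- "identity"
  }
  structure(list(value = value, scale = scale, measure = measure),
            class = "analysis_scale_value")
}

#' @rdname to_analysis_scale
#' @export
from_analysis_scale <- function(value, measure) {
  measure <- match.arg(measure, c(.ratio_measures, "MD"))
  if (measure %in% .ratio_measures) exp(value) else value
}

analysis_scale_of <- function(measure) {
  if (measure %in% .ratio_measures) "log" else "identity"
}

#' Standard error from a confidence interval
#'
#' `SE = (g(upper) - g(lower)) / (2 z)` with `z = qnorm((1 + level)/2)` and
#' `g` the scale transform (log for ratio measures, identity otherwise).
#'
#' @param ci_lower,ci_upper ordered confidence limits on the reporting scale.
#' @param ci_level confidence level in (0, 1); default 0.95.
#' @param scale `"log"` or `"identity"`.
#' @return the standard error on the analysis scale (always positive).
#' @examples
#' se_from_ci(0.86, 0.998)           # 0.0380 for a hazard/odds ratio
#' se_from_ci(-1, 3, scale = "identity")
#' @export
se_from_ci <- function(ci_lower, ci_upper, ci_level = 0.95,
                       scale = c("log", "identity")) {
  scale <- match.arg(scale)
  if (ci_level <= 0 || ci_level >= 1)
    stop("'ci_level' must be in (0, 1)", call. = FALSE)
  if (ci_lower >= ci_upper)
    stop("confidence limits must be ordered", call. = FALSE)
  if (scale == "log" && ci_lower <= 0)
    stop("log-scale limits must be positive", call. = FALSE)
  g <- if (scale == "log") log else identity
  (g(ci_upper) - g(ci_lower)) / (2 * stats::qnorm((1 + ci_level) / 2))
}

#' Confidence interval from an analysis-scale estimate and SE
#'
#' Inverse of [se_from_ci()]: Wald limits `theta +/- z SE`, back-transformed
#' to the reporting scale when `scale = "log"`.
#'
#' @param theta estimate on the analysis scale.
#' @param se standard error (> 0).
#' @param ci_level confidence level; default 0.95.
#' @param scale `"log"` or `"identity"`.
#' @return numeric vector `c(lower, upper)` on the reporting scale.
#' @export
ci_from_se <- function(theta, se, ci_level = 0.95,
                       scale = c("log", "identity")) {
  scale <- match.arg(scale)
  if (se <= 0) stop("'se' must be positive", call. = FALSE)
  z <- stats::qnorm((1 + ci_level) / 2)
  lim <- theta + c(-1, 1) * z * se
  if (scale == "log") exp(lim) else lim
}

#' Two-sided Wald P-value from an analysis-scale estimate and SE
#'
#' `P = 2 (1 - Phi(|theta| / SE))`.
#'
#' @param theta estimate on the analysis scale (an
#'   `"analysis_scale_value"` or a bare number).
#' @param se standard error (> 0).
#' @return a two-sided P-value in (0, 1].
#' @export
p_from_estimate <- function(theta, se) {
  if (inherits(theta, "analysis_scale_value")) theta <- theta$value
  if (se <= 0) stop("'se' must be positive", call. = FALSE)
  2 * stats::pnorm(-abs(theta) / se)
}

#' Standard error from a two-sided P-value
#'
#' Inverse of [p_from_estimate()]: `SE = |theta| / qnorm(1 - p/2)`.
#' Undefined when `theta = 0` or `p >= 1`.
#'
#' @param theta nonzero estimate on the analysis scale.
#' @param p_two_sided P-value in (0, 1).
#' @return the implied standard error.
#' @export
se_from_p <- function(theta, p_two_sided) {
  if (inherits(theta, "analysis_scale_value")) theta <- theta$value
  if (theta == 0) stop("SE from P is undefined at a null estimate", call. = FALSE)
  if (p_two_sided <= 0 || p_two_sided >= 1)
    stop("'p_two_sided' must be in (0, 1)", call. = FALSE)
  abs(theta) / stats::qnorm(1 - p_two_sided / 2)
}

#' A 2x2 table of trial events
#'
#' @param events_experimental,nonevents_experimental,events_control,nonevents_control
#'   non-negative cell counts.
#' @return an object of class `"two_by_two"`.
#' @examples
#' two_by_two(202, 194, 173, 229)  # severe-sepsis starch trial
#' @export
two_by_two <- function(events_experimental, nonevents_experimental,
                       events_control, nonevents_control) {
  cells <- c(events_experimental, nonevents_experimental,
             events_control, nonevents_control)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  if (events_experimental + nonevents_experimental == 0 ||
      events_control + nonevents_control == 0)
    stop("each arm must contain at least one participant", call. = FALSE)
  structure(list(events_experimental = events_experimental,
                 nonevents_experimental = nonevents_experimental,
                 events_control = events_control,
                 nonevents_control = nonevents_control),
            class = "two_by_two")
}

#' Effect measures from a 2x2 table
#'
#' Odds ratio `(a d)/(b c)` with Woolf standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)` on the log scale, plus arm risks, risk
#' ratio and risk difference.  When any cell is zero a Haldane–Anscombe
#' continuity correction (adding `correction`, default 0.5, to all four
#' cells) is applied to the odds-ratio quantities and flagged in the result.
#'
#' @param t a [two_by_two()] table.
#' @param correction value added to every cell when a zero cell is present.
#' @return a list with `or`, `log_or`, `se_log_or`, `rr`,
#'   `risk_experimental`, `risk_control`, `risk_difference` and
#'   `continuity_corrected`.
#' @examples
#' effects_from_table(two_by_two(202, 194, 173, 229))$se_log_or  # 0.1423
#' @export
effects_from_table <- function(t, correction = 0.5) {
  stopifnot(inherits(t, "two_by_two"))
  a <- t$events_experimental; b <- t$nonevents_experimental
  c <- t$events_control;      d <- t$nonevents_control
  n1 <- a + b; n0 <- c + d
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) {
    a <- a + correction; b <- b + correction
    c <- c + correction; d <- d + correction
  }
  or <- (a * d) / (b * c)
  list(or = or,
       log_or = log(or),
       se_log_or = sqrt(1 / a + 1 / b + 1 / c + 1 / d),
       rr = (a / (a + b)) / (c / (c + d)),
       risk_experimental = t$events_experimental / n1,
       risk_control = t$events_control / n0,
       risk_difference = t$events_experimental / n1 - t$events_control / n0,
       continuity_corrected = corrected)
}

#' Convert a risk ratio to an odds ratio at a given control-group risk
#'
#' `OR = (RR p0 / (1 - RR p0)) / (p0 / (1 - p0))`.  This is how a
#' sample-size calculation stated as "control risk p0, relative risk RR"
#' is placed on the log-odds analysis scale.
#'
#' @param rr risk ratio (> 0).
#' @param control_risk control-group event risk in (0, 1).
#' @return the corresponding odds ratio.
#' @examples
#' rr_to_or(0.90, 0.20)  # 0.878
#' rr_to_or(0.80, 0.50)  # 0.667
#' @export
rr_to_or <- function(rr, control_risk) {
  if (rr <= 0) stop("'rr' must be positive", call. = FALSE)
  if (control_risk <= 0 || control_risk >= 1)
    stop("'control_risk' must be in (0, 1)", call. = FALSE)
  p1 <- rr * control_risk
  if (p1 >= 1) stop("experimental risk rr * control_risk must be < 1", call. = FALSE)
  (p1 / (1 - p1)) / (control_risk / (1 - control_risk))
}

#' Resolve an effect estimate to (theta, SE, P) on the analysis scale
#'
#' The precision source is chosen in the order CI > SE > P (the CI is
#' authoritative when several are present).  When both a CI and a P-value
#' are supplied, the SE implied by each is compared and a warning is issued
#' if they disagree by more than `tol` in relative terms (published inputs
#' are usually rounded); the provenance of the SE actually used is recorded.
#'
#' @param est an [effect_estimate()].
#' @param tol relative disagreement between CI-derived and P-derived SE that
#'   triggers a warning; default 0.10.
#' @return a list with `theta`, `se`, `p`, `ci` (analysis-scale limits),
#'   `scale`, `measure` and `se_source` (`"ci"`, `"se"` or `"p"`).
#' @export
resolve_estimate <- function(est, tol = 0.10) {
  stopifnot(inherits(est, "effect_estimate"))
  asv <- to_analysis_scale(est)
  theta <- asv$value
  scale <- asv$scale
  has_ci <- !is.null(est$ci_lower) && !is.null(est$ci_upper)
  se_ci <- if (has_ci)
    se_from_ci(est$ci_lower, est$ci_upper, est$ci_level, scale) else NULL
  se_p <- if (!is.null(est$p) && est$p < 1 && theta != 0)
    se_from_p(theta, est$p) else NULL
  if (!is.null(se_ci)) {
    se <- se_ci; se_source <- "ci"
    if (!is.null(se_p) && abs(se_p - se_ci) / se_ci > tol)
      warning(sprintf(
        "SE from CI (%.4g) and from P (%.4g) disagree by more than %.0f%%; using the CI",
        se_ci, se_p, 100 * tol), call. = FALSE)
  } else if (!is.null(est$se)) {
    se <- est$se; se_source <- "se"
  } else if (!is.null(se_p)) {
    se <- se_p; se_source <- "p"
  } else {
    stop("cannot resolve a standard error from the supplied fields", call. = FALSE)
  }
  p <- if (!is.null(est$p)) est$p else p_from_estimate(theta, se)
  g <- if (scale == "log") log else identity
  ci <- if (has_ci) c(g(est$ci_lower), g(est$ci_upper))
        else theta + c(-1, 1) * stats::qnorm((1 + est$ci_level) / 2) * se
  list(theta = theta, se = se, p = p, ci = ci,
       scale = scale, measure = est$measure, se_source = se_source)
}
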