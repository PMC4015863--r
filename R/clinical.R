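#' Clinical significance (step 5)
#'
#' Once all four statistical steps have passed and the Bayes factor is
#' below its threshold, the size of the effect is judged clinically:
#' number-needed-to-treat/harm for binary outcomes and comparison against
#' the minimal clinically relevant difference (MCID) that underpinned the
#' sample-size calculation.
#'
#' @name clinical
NULL

#' Number needed to treat or harm
#'
#' The reciprocal of the absolute risk difference, rounded up
#' (conservatively) to a whole number of patients.  Whether the result is
#' an NNT (benefit) or NNH (harm) depends on the direction of the risk
#' change relative to the declared direction of benefit.
#'
#' @param risk_control,risk_experimental event risks in `[0, 1]`.
#' @param direction_of_benefit `"less_than_null"` (default: fewer events is
#'   better, e.g. mortality) or `"greater_than_null"` (more events is
#'   better, e.g. recovery).
#' @return a list with integer `value` (>= 1) and `kind` (`"NNT"`/`"NNH"`).
#' @examples
#' nnt_nnh(0.43, 0.51)  # NNH 13: one extra harmed per 13 treated
#' nnt_nnh(0.20, 0.18)  # NNT 50
#' @export
nnt_nnh <- function(risk_control, risk_experimental,
                    direction_of_benefit = c("less_than_null",
                                             "greater_than_null")) {
  direction_of_benefit <- match.arg(direction_of_benefit)
  for (r in c(risk_control, risk_experimental))
    if (r < 0 || r > 1) stop("risks must be in [0, 1]", call. = FALSE)
  rd <- risk_experimental - risk_control
  if (rd == 0) stop("zero risk difference: NNT is undefined", call. = FALSE)
  improved <- if (direction_of_benefit == "less_than_null") rd < 0 else rd > 0
  list(value = as.integer(ceiling(1 / abs(rd))),
       kind = if (improved) "NNT" else "NNH")
}

#' Gate on assessing clinical significance
#'
#' Clinical significance is only assessed when all four statistical steps
#' passed and the Bayes factor is strictly below its threshold; assessing
#' it after a failed statistical assessment invites erroneous
#' interpretation.
#'
#' @param step_passed logical vector of length 4: verdicts of steps 1-4.
#' @param bf the primary outcome's Bayes factor.
#' @param threshold Bayes-factor threshold; default 0.1.
#' @return `TRUE` iff clinical significance may be assessed.
#' @export
clinical_gate <- function(step_passed, bf, threshold = 0.1) {
  if (length(step_passed) != 4 || anyNA(step_passed))
    stop("verdicts for all four statistical steps are required", call. = FALSE)
  all(step_passed) && bf < threshold
}

#' Compare an effect against the minimal clinically relevant difference
#'
#' Both quantities must be on the analysis scale; the sign of `mcid`
#' encodes the benefit direction.  `mcid_met` is inclusive (an estimate
#' exactly at the MCID counts); `ci_excludes_mcid_shortfall` additionally
#' requires the whole confidence interval to be at least as extreme as the
#' MCID.
#'
#' @param theta point estimate on the analysis scale.
#' @param ci_lower,ci_upper confidence limits on the analysis scale.
#' @param mcid nonzero minimal clinically relevant difference on the same
#'   scale.
#' @return a list with logicals `mcid_met` and `ci_excludes_mcid_shortfall`.
#' @export
compare_to_mcid <- function(theta, ci_lower, ci_upper, mcid) {
  if (mcid == 0) stop("'mcid' must be nonzero", call. = FALSE)
  if (ci_lower > ci_upper) stop("confidence limits must be ordered", call. = FALSE)
  if (mcid < 0) {
    list(mcid_met = theta <= mcid, ci_excludes_mcid_shortfall = ci_upper <= mcid)
  } else {
    list(mcid_met = theta >= mcid, ci_excludes_mcid_shortfall = ci_lower >= mcid)
  }
}
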