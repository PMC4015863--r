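#' Sample-size and power calculations
#'
#' Normal-approximation two-group calculations.  These define the
#' alternative hypothesis used by the Bayes factor, the information
#' fraction used by the sequential adjustment, and the confirmatory /
#' exploratory status of secondary outcomes.
#'
#' @name design
NULL

#' Sample size for comparing two proportions
#'
#' Normal-approximation (unpooled-variance) formula without continuity
#' correction: with allocation ratio `r = n_control / n_experimental`,
#' \deqn{n_{exp} = (z_{1-\alpha/2} + z_{power})^2
#'   \left(p_1(1-p_1) + p_0(1-p_0)/r\right) / (p_0 - p_1)^2}
#' rounded up per group.
#'
#' @param p0 control-group event risk in (0, 1).
#' @param p1 experimental-group event risk in (0, 1), different from `p0`.
#' @param alpha two-sided type-I error; default 0.05.
#' @param power target power; default 0.80.
#' @param allocation_ratio controls-per-experimental participant; default 1.
#' @return a list with `n_experimental`, `n_control`, `n_per_group`
#'   (when the ratio is 1) and `n_total`.
#' @examples
#' sample_size_two_proportions(0.50, 0.40)              # 385 per group
#' sample_size_two_proportions(0.50, 0.40, power = 0.9) # 515 per group
#' @export
sample_size_two_proportions <- function(p0, p1, alpha = 0.05, power = 0.80,
                                        allocation_ratio = 1) {
  check_risk(p0, "p0"); check_risk(p1, "p1")
  if (p0 == p1) stop("p0 == p1: required sample size is infinite", call. = FALSE)
  if (allocation_ratio <= 0) stop("'allocation_ratio' must be > 0", call. = FALSE)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  r <- allocation_ratio
  n_exp <- ceiling(z^2 * (p1 * (1 - p1) + p0 * (1 - p0) / r) / (p0 - p1)^2)
  n_ctrl <- ceiling(r * z^2 * (p1 * (1 - p1) + p0 * (1 - p0) / r) / (p0 - p1)^2)
  out <- list(n_experimental = n_exp, n_control = n_ctrl,
              n_total = n_exp + n_ctrl)
  if (r == 1) out$n_per_group <- n_exp
  out
}

#' Sample size for a mean difference
#'
#' `n per group = 2 (z_{1-alpha/2} + z_{power})^2 sd^2 / delta^2`, rounded up.
#'
#' @param delta nonzero anticipated mean difference.
#' @param sd common outcome standard deviation (> 0).
#' @param alpha two-sided type-I error; default 0.05.
#' @param power target power; default 0.90.
#' @return a list with `n_per_group` and `n_total`.
#' @examples
#' sample_size_mean_difference(0.5, 1, power = 0.90)  # 85 per group
#' @export
sample_size_mean_difference <- function(delta, sd, alpha = 0.05, power = 0.90) {
  if (delta == 0) stop("delta = 0: required sample size is infinite", call. = FALSE)
  if (sd <= 0) stop("'sd' must be positive", call. = FALSE)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n <- ceiling(2 * z^2 * sd^2 / delta^2)
  list(n_per_group = n, n_total = 2 * n)
}

#' Power of the two-proportion comparison at a given size
#'
#' Normal-approximation power of the two-sided level-`alpha` Wald test with
#' `n_per_group` experimental participants and
#' `allocation_ratio * n_per_group` controls.
#'
#' @inheritParams sample_size_two_proportions
#' @param n_per_group experimental-arm size (>= 2).
#' @return the approximate power in (0, 1).
#' @export
power_two_proportions <- function(p0, p1, n_per_group, alpha = 0.05,
                                  allocation_ratio = 1) {
  check_risk(p0, "p0"); check_risk(p1, "p1")
  if (n_per_group < 2) stop("'n_per_group' must be at least 2", call. = FALSE)
  se <- sqrt(p1 * (1 - p1) / n_per_group +
             p0 * (1 - p0) / (allocation_ratio * n_per_group))
  za <- stats::qnorm(1 - alpha / 2)
  d <- abs(p0 - p1) / se
  stats::pnorm(d - za) + stats::pnorm(-d - za)
}

check_risk <- function(p, name) {
  if (p <= 0 || p >= 1)
    stop(sprintf("'%s' must be in (0, 1)", name), call. = FALSE)
}

#' Information fraction of a trial
#'
#' Randomised participants divided by the planned total, clamped to 1 (a
#' trial that over-recruits has full information); a message notes the
#' clamping.
#'
#' @param n_randomised participants randomised (> 0).
#' @param planned_n_total planned total sample size (> 0).
#' @return a value in (0, 1].
#' @examples
#' information_fraction(250, 500)     # 0.5
#' information_fraction(20211, 20000) # 1 (clamped)
#' @export
information_fraction <- function(n_randomised, planned_n_total) {
  if (planned_n_total <= 0) stop("'planned_n_total' must be positive", call. = FALSE)
  if (n_randomised <= 0) stop("'n_randomised' must be positive", call. = FALSE)
  f <- n_randomised / planned_n_total
  if (f > 1) {
    message("n_randomised exceeds the planned total; information fraction clamped to 1")
    f <- 1
  }
  f
}

#' Confirmatory or exploratory status of an outcome
#'
#' An outcome analysed with less than 80% power (given its anticipated
#' effect and variability at the achieved sample size) should be treated
#' as exploratory; 80% or more is confirmatory (inclusive boundary).
#'
#' @param power the outcome's power in (0, 1), e.g. from
#'   [power_two_proportions()].
#' @param outcome_id optional label carried through to the result.
#' @param cutoff confirmatory power cutoff; default 0.80.
#' @return a list with `outcome_id`, `power` and `status`
#'   (`"confirmatory"` or `"exploratory"`).
#' @export
assess_outcome_power <- function(power, outcome_id = NULL, cutoff = 0.80) {
  if (is.null(power) || !is.finite(power) || power <= 0 || power >= 1)
    stop("a computed power in (0, 1) is required", call. = FALSE)
  list(outcome_id = outcome_id, power = power,
       status = if (power >= cutoff) "confirmatory" else "exploratory")
}
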