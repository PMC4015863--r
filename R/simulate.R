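#' Synthetic two-arm trials and Monte-Carlo calibration harnesses
#'
#' Generates binary-outcome two-arm trials at the count level (no normal
#' approximation on the data side) and estimates rejection rates, power,
#' familywise error and Bayes-factor operating characteristics by
#' simulation.  Every stochastic output carries its Monte-Carlo standard
#' error, and everything is reproducible under an explicit seed.
#'
#' @name simulate
NULL

#' Simulate one two-arm binary trial
#'
#' Event counts are drawn binomially with control risk `p_control` and
#' experimental risk `rr * p_control`.  Replicate `k` of a study is
#' reproducible in isolation: its stream is seeded with `seed + replicate`.
#'
#' @param p_control control-group event risk in (0, 1).
#' @param rr true risk ratio; experimental risk `rr * p_control` must lie
#'   in `[0, 1]`.
#' @param n_per_arm participants per arm.
#' @param seed base random seed (required).
#' @param replicate replicate counter; default 1.
#' @return a [two_by_two()] table.
#' @export
simulate_binary_trial <- function(p_control, rr, n_per_arm, seed, replicate = 1) {
  check_risk(p_control, "p_control")
  p1 <- rr * p_control
  if (p1 < 0 || p1 > 1)
    stop("experimental risk rr * p_control must be in [0, 1]", call. = FALSE)
  if (missing(seed)) stop("'seed' is required for reproducibility", call. = FALSE)
  set.seed(seed + replicate)
  e1 <- stats::rbinom(1, n_per_arm, p1)
  e0 <- stats::rbinom(1, n_per_arm, p_control)
  two_by_two(e1, n_per_arm - e1, e0, n_per_arm - e0)
}

# vectorised draws for the batch harnesses: one matrix of event counts
sim_counts <- function(p_control, rr, n_per_arm, replicates, seed) {
  p1 <- rr * p_control
  if (p1 < 0 || p1 > 1)
    stop("experimental risk rr * p_control must be in [0, 1]", call. = FALSE)
  set.seed(seed)
  cbind(e1 = stats::rbinom(replicates, n_per_arm, p1),
        e0 = stats::rbinom(replicates, n_per_arm, p_control))
}

# vectorised Wald log-OR statistics; 0.5 continuity correction on any
# table with a zero cell (same convention as effects_from_table)
wald_log_or <- function(e1, e0, n_per_arm) {
  a <- e1; b <- n_per_arm - e1; c <- e0; d <- n_per_arm - e0
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  a <- a + 0.5 * zero; b <- b + 0.5 * zero
  c <- c + 0.5 * zero; d <- d + 0.5 * zero
  list(log_or = log(a * d / (b * c)),
       se = sqrt(1 / a + 1 / b + 1 / c + 1 / d))
}

#' Monte-Carlo rejection rate of an analysis procedure
#'
#' Simulates `replicates` two-arm binary trials and reports the fraction
#' in which `analysis` rejects.  Under `rr = 1` this estimates type-I
#' error; under the design's anticipated `rr` at the designed sample size
#' it estimates power.
#'
#' @inheritParams simulate_binary_trial
#' @param replicates number of simulated trials (>= 100).
#' @param analysis either the string `"wald"` (two-sided Wald log-OR test
#'   at `alpha`) or a function taking vectors `(log_or, se)` and returning
#'   a logical rejection vector.
#' @param alpha two-sided alpha for the built-in Wald analysis.
#' @return a list with `rejection_rate`, `mc_se` and `replicates`.
#' @export
estimate_type1_and_power <- function(p_control, rr, n_per_arm, replicates,
                                     seed, analysis = "wald", alpha = 0.05) {
  check_risk(p_control, "p_control")
  if (replicates < 100) stop("use at least 100 replicates", call. = FALSE)
  counts <- sim_counts(p_control, rr, n_per_arm, replicates, seed)
  w <- wald_log_or(counts[, "e1"], counts[, "e0"], n_per_arm)
  reject <- if (is.function(analysis)) analysis(w$log_or, w$se)
            else abs(w$log_or / w$se) > stats::qnorm(1 - alpha / 2)
  r <- mean(reject)
  list(rejection_rate = r, mc_se = sqrt(r * (1 - r) / replicates),
       replicates = replicates)
}

#' Bayes-factor operating characteristics by simulation
#'
#' Simulates trials under a chosen true risk ratio and reports the
#' proportion of replicates whose Bayes factor (against `theta_alt`)
#' falls below `threshold`.  Run once under the design's anticipated
#' effect and once under the null to see both sides of the calibration.
#'
#' @inheritParams estimate_type1_and_power
#' @param theta_alt alternative-hypothesis log odds ratio.
#' @param threshold Bayes-factor threshold; default 0.1.
#' @return a list with `prop_bf_below_threshold`, `mc_se` and `replicates`.
#' @export
bf_operating_characteristics <- function(p_control, rr, n_per_arm, replicates,
                                         seed, theta_alt, threshold = 0.1) {
  if (theta_alt == 0) stop("'theta_alt' must be nonzero", call. = FALSE)
  counts <- sim_counts(p_control, rr, n_per_arm, replicates, seed)
  w <- wald_log_or(counts[, "e1"], counts[, "e0"], n_per_arm)
  log_bf <- (theta_alt^2 - 2 * w$log_or * theta_alt) / (2 * w$se^2)
  prop <- mean(log_bf < log(threshold))
  list(prop_bf_below_threshold = prop,
       mc_se = sqrt(prop * (1 - prop) / replicates),
       replicates = replicates)
}

#' Monte-Carlo familywise error of a sequential testing scheme
#'
#' Simulates the canonical score process under the global null at the
#' given information fractions and reports the probability that the
#' standardised statistic ever exceeds its look-wise boundary.  With
#' `z_bounds = rep(qnorm(0.975), K)` this demonstrates the inflation from
#' naive repeated testing; with O'Brien-Fleming boundaries it verifies
#' restoration of the nominal level.
#'
#' @param fractions increasing information fractions in (0, 1].
#' @param z_bounds two-sided critical values, one per look.
#' @param replicates number of simulated trajectories.
#' @param seed random seed.
#' @return a list with `rejection_rate`, `mc_se` and `replicates`.
#' @export
simulate_sequential_rejection <- function(fractions, z_bounds, replicates, seed) {
  K <- length(fractions)
  stopifnot(length(z_bounds) == K, all(diff(fractions) > 0))
  set.seed(seed)
  dt <- diff(c(0, fractions))
  inc <- matrix(stats::rnorm(replicates * K), replicates, K)
  s <- inc %*% diag(sqrt(dt), K) # score increments
  s <- t(apply(s, 1, cumsum))
  if (K == 1) s <- matrix(s, ncol = 1)
  z <- sweep(s, 2, sqrt(fractions), "/")
  reject <- rowSums(abs(z) >= matrix(z_bounds, replicates, K, byrow = TRUE)) > 0
  r <- mean(reject)
  list(rejection_rate = r, mc_se = sqrt(r * (1 - r) / replicates),
       replicates = replicates)
}
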