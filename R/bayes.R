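#' Gaussian likelihood-ratio Bayes factor for a trial result
#'
#' The ratio of the likelihood of the observed effect under the null
#' hypothesis (effect = 0) to its likelihood under a point alternative --
#' the intervention effect hypothesised in the trial's sample-size
#' calculation -- both evaluated with the same Gaussian kernel:
#'
#' \deqn{BF = \frac{\exp(-\hat\theta^2 / 2 SE^2)}
#'                 {\exp(-(\hat\theta - \theta_A)^2 / 2 SE^2)}}
#'
#' so \eqn{\log BF = (\theta_A^2 - 2\hat\theta\theta_A)/(2 SE^2)}.
#' Values below 1 favour the alternative, above 1 the null; `BF = 1`
#' exactly when the observed effect sits halfway between 0 and
#' `theta_alt`.  Directionality is preserved: an observed effect opposite
#' in sign to the anticipated benefit yields a very large BF.
#'
#' @param theta_obs observed effect on the analysis scale (log-ratio or
#'   mean difference).
#' @param se standard error of `theta_obs` (> 0).
#' @param theta_alt nonzero alternative-hypothesis effect on the same scale.
#' @param threshold classification threshold; BF below it is taken to
#'   support the alternative, above `1/threshold` to support the null.
#'   Default 0.1.
#' @return an object of class `"bayes_factor"`: a list with `bf`, `log_bf`,
#'   `theta_obs`, `se`, `theta_alt`, `threshold` and `classification`
#'   (`"supports_alternative"`, `"equivocal"` or `"supports_null"`).
#' @examples
#' bayes_factor(-0.12, 0.04, -0.11)   # 0.011 -> supports the alternative
#' bayes_factor(0.30, 0.142, -0.40)   # about 20,306 -> supports the null
#' bayes_factor(-0.11 / 2, 0.04, -0.11)$bf  # exactly 1
#' @export
bayes_factor <- function(theta_obs, se, theta_alt, threshold = 0.1) {
  if (se <= 0) stop("'se' must be positive", call. = FALSE)
  if (theta_alt == 0)
    stop("'theta_alt' must be nonzero (degenerate alternative)", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("'threshold' must be in (0, 1)", call. = FALSE)
  log_bf <- (theta_alt^2 - 2 * theta_obs * theta_alt) / (2 * se^2)
  bf <- exp(log_bf)
  classification <- if (bf < threshold) "supports_alternative"
                    else if (bf > 1 / threshold) "supports_null"
                    else "equivocal"
  structure(list(bf = bf, log_bf = log_bf,
                 theta_obs = theta_obs, se = se, theta_alt = theta_alt,
                 threshold = threshold, classification = classification),
            class = "bayes_factor")
}

#' @export
print.bayes_factor <- function(x, ...) {
  cat("Gaussian likelihood-ratio Bayes factor (null vs alternative)\n")
  cat(sprintf("  observed effect (analysis scale): %.4g  (SE %.4g)\n",
              x$theta_obs, x$se))
  cat(sprintf("  alternative hypothesis:           %.4g\n", x$theta_alt))
  cat(sprintf("  Bayes factor: %s   [%s at threshold %g]\n",
              format_bf(x$bf), gsub("_", " ", x$classification), x$threshold))
  invisible(x)
}

format_bf <- function(bf) {
  if (bf >= 1000) formatC(round(bf), format = "d", big.mark = ",")
  else formatC(bf, format = "g", digits = 3)
}

#' Sceptical alternative hypothesis
#'
#' When the sample-size calculation's anticipated effect is not grounded in
#' a systematic review, a second, smaller ("sceptical") alternative is
#' recommended: a ratio halfway between 1.0 and the hypothesised ratio.
#' The midpoint is taken on the ratio scale by default (`RR 0.80 -> 0.90`);
#' `midpoint = "log"` takes it on the log scale instead.
#'
#' @param original_ratio the hypothesised RR/OR/HR (not 1).
#' @param midpoint `"ratio"` (default) or `"log"`.
#' @return a list with the sceptical `ratio` and its `theta` (log ratio).
#' @examples
#' sceptical_alternative(0.80)  # ratio 0.90, theta log(0.90)
#' @export
sceptical_alternative <- function(original_ratio, midpoint = c("ratio", "log")) {
  midpoint <- match.arg(midpoint)
  if (is.null(original_ratio) || !is.finite(original_ratio))
    stop("an original ratio-scale effect is required", call. = FALSE)
  if (original_ratio <= 0) stop("ratio must be positive", call. = FALSE)
  if (original_ratio == 1)
    stop("no effect to halve: hypothesised ratio is 1", call. = FALSE)
  ratio <- if (midpoint == "ratio") (1 + original_ratio) / 2
           else exp(log(original_ratio) / 2)
  list(ratio = ratio, theta = log(ratio), source = "sceptical")
}

#' Bayes factor as a function of the observed effect
#'
#' Evaluates [bayes_factor()] over a grid of hypothetical observed effects
#' for fixed `theta_alt` and `se`; the curve equals 1 at `theta_alt / 2`
#' and is monotone in the observed effect (decreasing towards the
#' alternative when `theta_alt > 0`, increasing when `theta_alt < 0`).
#'
#' @param theta_alt nonzero alternative effect on the analysis scale.
#' @param se standard error (> 0).
#' @param grid numeric vector of observed-effect values.
#' @return a data frame with columns `theta` and `bf`.
#' @export
bf_curve <- function(theta_alt, se, grid) {
  if (se <= 0) stop("'se' must be positive", call. = FALSE)
  if (theta_alt == 0) stop("'theta_alt' must be nonzero", call. = FALSE)
  if (!all(is.finite(grid))) stop("'grid' must be finite", call. = FALSE)
  log_bf <- (theta_alt^2 - 2 * grid * theta_alt) / (2 * se^2)
  data.frame(theta = grid, bf = exp(log_bf))
}
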