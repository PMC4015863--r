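#' Group-sequential threshold adjustment
#'
#' When a trial stops before its planned sample size or analyses
#' accumulating data at interim looks, the significance threshold (and the
#' confidence level of the reported interval) must be adjusted.  This
#' module implements O'Brien-Fleming-type boundaries in two forms: the
#' classic boundary with a constant score-scale critical value, and the
#' Lan-DeMets O'Brien-Fleming-type alpha-spending function for arbitrary
#' information fractions.  Boundary crossing probabilities for the
#' correlated sequence of test statistics (corr = sqrt(t_i/t_j)) are
#' obtained by recursive numerical integration of the score process.
#'
#' @name sequential
NULL

#' O'Brien-Fleming-type alpha-spending function
#'
#' `alpha*(t) = 2 (1 - Phi(z_{1-alpha/2} / sqrt(t)))`: spends almost no
#' alpha early and the full two-sided `alpha` at `t = 1`.
#'
#' @param t information fraction in (0, 1].
#' @param alpha_total total two-sided alpha; default 0.05.
#' @return the cumulative alpha spent by information fraction `t`.
#' @examples
#' obf_spending(1, 0.05)    # 0.05
#' obf_spending(0.5, 0.05)  # 0.00557: mid-trial stopping needs P ~ 5 per mille
#' @export
obf_spending <- function(t, alpha_total = 0.05) {
  if (any(t <= 0)) stop("'t' must be positive", call. = FALSE)
  if (any(t > 1)) stop("'t' must not exceed 1", call. = FALSE)
  if (alpha_total <= 0 || alpha_total >= 1)
    stop("'alpha_total' must be in (0, 1)", call. = FALSE)
  2 * stats::pnorm(-stats::qnorm(1 - alpha_total / 2) / sqrt(t))
}

# Incremental two-sided boundary-crossing probabilities for the canonical
# score process S_k ~ N(0, t_k) with independent increments, given
# score-scale half-widths b_k = z_k * sqrt(t_k).  Recursion: the density of
# S_k restricted to the continuation region is propagated one look at a
# time by convolution with the N(0, t_{k+1} - t_k) increment kernel,
# integrated with composite Simpson weights.
gs_crossing <- function(fractions, z_bounds) {
  K <- length(fractions)
  stopifnot(length(z_bounds) == K, all(diff(fractions) > 0),
            fractions[1] > 0, fractions[K] <= 1)
  b <- z_bounds * sqrt(fractions)
  cross <- numeric(K)
  cross[1] <- 2 * stats::pnorm(-z_bounds[1])
  if (K == 1) return(cross)
  grid <- gs_grid(b[1], sqrt(fractions[1]))
  f <- stats::dnorm(grid$x, sd = sqrt(fractions[1]))
  for (k in 2:K) {
    dt <- fractions[k] - fractions[k - 1]
    mass <- sum(grid$w * f)
    new_grid <- gs_grid(b[k], sqrt(dt))
    # density of S_k on the new continuation region
    kern <- stats::dnorm(outer(new_grid$x, grid$x, "-"), sd = sqrt(dt))
    f_new <- as.vector(kern %*% (grid$w * f))
    cross[k] <- mass - sum(new_grid$w * f_new)
    grid <- new_grid
    f <- f_new
  }
  cross
}

# composite-Simpson grid over (-b, b); node count adapts to the increment
# kernel width so narrow convolutions stay resolved
gs_grid <- function(b, kernel_sd, base_n = 801L, max_n = 4001L) {
  n <- max(base_n, ceiling(2 * b / (kernel_sd / 8)))
  n <- min(as.integer(n), max_n)
  if (n %% 2L == 0L) n <- n + 1L
  x <- seq(-b, b, length.out = n)
  h <- x[2] - x[1]
  w <- rep(c(2, 4), length.out = n)
  w[1] <- w[n] <- 1
  list(x = x, w = w * h / 3)
}

#' O'Brien-Fleming group-sequential boundaries
#'
#' Two-sided symmetric boundaries for a schedule of information fractions.
#' `method = "obf_spending"` (default) allocates the cumulative alpha of
#' [obf_spending()] at each look, solving for each critical value by
#' recursive numerical integration; `method = "obf_classic"` uses the
#' constant score-scale boundary `z_k = c / sqrt(t_k)` with `c` chosen so
#' the total two-sided crossing probability equals `alpha_total`.
#'
#' @param fractions strictly increasing information fractions in (0, 1].
#' @param alpha_total total two-sided alpha; default 0.05.
#' @param method `"obf_spending"` or `"obf_classic"`.
#' @return an object of class `"gs_boundaries"`: a data frame with columns
#'   `fraction`, `z_boundary`, `nominal_p` (two-sided), and
#'   `cumulative_alpha_spent`.
#' @examples
#' gs_boundaries(c(0.5, 1))                       # spending form
#' gs_boundaries(c(0.5, 1), method = "obf_classic")  # z = (2.797, 1.977)
#' @export
gs_boundaries <- function(fractions, alpha_total = 0.05,
                          method = c("obf_spending", "obf_classic")) {
  method <- match.arg(method)
  if (length(fractions) < 1) stop("at least one look is required", call. = FALSE)
  if (any(fractions <= 0) || any(fractions > 1) || any(diff(fractions) <= 0))
    stop("'fractions' must be strictly increasing in (0, 1]", call. = FALSE)
  if (alpha_total <= 0 || alpha_total >= 1)
    stop("'alpha_total' must be in (0, 1)", call. = FALSE)
  K <- length(fractions)
  if (method == "obf_spending") {
    target <- obf_spending(fractions, alpha_total)
    z <- numeric(K)
    z[1] <- stats::qnorm(1 - target[1] / 2)
    if (K > 1) {
      for (k in 2:K) {
        increment <- target[k] - target[k - 1]
        fk <- fractions[1:k]
        obj <- function(zk) sum(gs_crossing(fk, c(z[1:(k - 1)], zk))) - target[k]
        # crossing probability is decreasing in z_k
        z[k] <- stats::uniroot(obj, c(0.1, 12), tol = 1e-9)$root
        if (increment <= 0) z[k] <- max(z[k], z[k - 1])
      }
    }
  } else {
    total <- function(cc) sum(gs_crossing(fractions, cc / sqrt(fractions))) -
      alpha_total
    cc <- stats::uniroot(total, c(stats::qnorm(1 - alpha_total / 2) - 1e-6, 12),
                         tol = 1e-9)$root
    z <- cc / sqrt(fractions)
  }
  spent <- cumsum(gs_crossing(fractions, z))
  out <- data.frame(fraction = fractions, z_boundary = z,
                    nominal_p = 2 * stats::pnorm(-z),
                    cumulative_alpha_spent = spent)
  structure(out, class = c("gs_boundaries", "data.frame"),
            method = method, alpha_total = alpha_total)
}

#' @export
print.gs_boundaries <- function(x, ...) {
  cat(sprintf("O'Brien-Fleming boundaries (%s), two-sided alpha %.4g\n",
              attr(x, "method"), attr(x, "alpha_total")))
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Confidence level matching an adjusted significance threshold
#'
#' The interval reported at a look with a two-sided nominal threshold `p`
#' should be widened to the `1 - p` level (repeated-confidence-interval
#' style), so that interval and threshold agree.
#'
#' @param nominal_p_at_look two-sided nominal threshold in (0, 1).
#' @return the confidence level `1 - nominal_p_at_look`.
#' @examples
#' adjusted_ci_level(0.05)     # 0.95
#' adjusted_ci_level(0.00557)  # 0.99443
#' @export
adjusted_ci_level <- function(nominal_p_at_look) {
  if (nominal_p_at_look <= 0 || nominal_p_at_look >= 1)
    stop("'nominal_p_at_look' must be in (0, 1)", call. = FALSE)
  1 - nominal_p_at_look
}

#' Sequential adjustment of a trial's significance threshold (step 3)
#'
#' If the planned sample size was reached and no interim analyses were
#' performed, the design alpha applies unchanged.  Otherwise the required
#' threshold is the O'Brien-Fleming nominal P at the achieved information
#' fraction: from the full boundary set when planned look fractions are
#' given, or from the spending function alone for a single unplanned early
#' stop.
#'
#' @param p_observed observed two-sided P-value for the outcome.
#' @param fraction achieved information fraction, e.g. from
#'   [information_fraction()].
#' @param alpha design two-sided alpha; default 0.05.
#' @param planned_fractions optional increasing schedule of interim-look
#'   fractions.  If the achieved fraction is not among them it is appended
#'   as the final analysis.
#' @param interim_looks_performed number of interim analyses actually
#'   conducted before the final one; default 0.
#' @return a list with `required_threshold`, `met` (logical),
#'   `adjusted_ci_level` and `adjusted` (whether any adjustment applied).
#' @examples
#' apply_sequential_adjustment(0.0035, information_fraction(20211, 20000))
#' apply_sequential_adjustment(0.04, 0.5)  # mid-trial stop: 0.04 fails
#' @export
apply_sequential_adjustment <- function(p_observed, fraction, alpha = 0.05,
                                        planned_fractions = NULL,
                                        interim_looks_performed = 0) {
  if (p_observed <= 0 || p_observed > 1)
    stop("'p_observed' must be in (0, 1]", call. = FALSE)
  if (fraction <= 0 || fraction > 1)
    stop("'fraction' must be in (0, 1]", call. = FALSE)
  full_information <- fraction >= 1 - 1e-12
  no_looks <- interim_looks_performed == 0 &&
    (is.null(planned_fractions) || length(planned_fractions) == 0)
  if (full_information && no_looks) {
    threshold <- alpha
    adjusted <- FALSE
  } else if (!is.null(planned_fractions) && length(planned_fractions) > 0) {
    sched <- planned_fractions[planned_fractions < fraction - 1e-12]
    sched <- c(sched, fraction)
    bounds <- gs_boundaries(sched, alpha)
    threshold <- bounds$nominal_p[length(sched)]
    adjusted <- TRUE
  } else {
    # single unplanned early stop: spend the fraction's cumulative alpha
    threshold <- obf_spending(fraction, alpha)
    adjusted <- TRUE
  }
  list(required_threshold = threshold,
       met = p_observed < threshold,
       adjusted_ci_level = adjusted_ci_level(threshold),
       adjusted = adjusted)
}
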