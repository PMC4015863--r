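#' Multiplicity adjustment across outcome comparisons (step 4)
#'
#' Strong familywise-error control when a trial declares success if any one
#' of several outcome comparisons is significant.  Four procedures are
#' offered: Bonferroni, Hommel (closed testing with Simes local tests,
#' uniformly less conservative than Bonferroni), the fixed-sequence
#' procedure (hierarchical testing at full alpha, stopping at the first
#' failure), and the fallback procedure (weighted alpha that accumulates
#' along the hierarchy and never stops).
#'
#' @param p_raw numeric vector of raw two-sided P-values in (0, 1].
#' @param procedure one of `"hommel"`, `"bonferroni"`, `"fixed_sequence"`,
#'   `"fallback"`, `"none"`.
#' @param alpha familywise two-sided alpha; default 0.05.
#' @param weights for `"fallback"`: non-negative weights summing to 1, one
#'   per comparison in hierarchy order.
#' @param ids optional comparison labels.
#' @return a data frame with one row per comparison: `id`, `p_raw`,
#'   `p_adjusted` (NA where the procedure defines none), `local_alpha`
#'   (NA for Hommel, which has no per-comparison threshold), `tested` and
#'   `rejected`.  Input order is preserved; for the sequence-based
#'   procedures input order is the hierarchy order.
#' @examples
#' adjust_family(c(0.01, 0.04, 0.20, 0.03), "fixed_sequence")
#' adjust_family(c(0.01, 0.04), "fallback", weights = c(0.5, 0.5))
#' adjust_family(c(0.01, 0.50), "hommel")
#' @export
adjust_family <- function(p_raw,
                          procedure = c("hommel", "bonferroni",
                                        "fixed_sequence", "fallback", "none"),
                          alpha = 0.05, weights = NULL, ids = NULL) {
  procedure <- match.arg(procedure)
  m <- length(p_raw)
  if (m < 1) stop("the comparison family is empty", call. = FALSE)
  if (any(p_raw <= 0 | p_raw > 1))
    stop("P-values must be in (0, 1]", call. = FALSE)
  if (is.null(ids)) ids <- paste0("H", seq_len(m))
  tested <- rep(TRUE, m)
  local_alpha <- rep(NA_real_, m)
  switch(procedure,
    bonferroni = {
      p_adj <- stats::p.adjust(p_raw, method = "bonferroni")
      local_alpha <- rep(alpha / m, m)
      rejected <- p_adj < alpha
    },
    hommel = {
      p_adj <- stats::p.adjust(p_raw, method = "hommel")
      rejected <- p_adj < alpha
    },
    fixed_sequence = {
      p_adj <- cummax(p_raw)
      pass <- p_raw < alpha
      first_fail <- match(FALSE, pass, nomatch = m + 1L)
      tested <- seq_len(m) <= first_fail
      rejected <- pass & tested
      local_alpha <- ifelse(tested, alpha, NA_real_)
      p_adj[!tested] <- NA_real_
    },
    fallback = {
      if (is.null(weights) || length(weights) != m)
        stop("'fallback' needs one weight per comparison", call. = FALSE)
      if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
        stop("weights must be non-negative and sum to 1", call. = FALSE)
      rejected <- logical(m)
      carried <- 0
      for (i in seq_len(m)) {
        local_alpha[i] <- weights[i] * alpha + carried
        rejected[i] <- local_alpha[i] > 0 && p_raw[i] < local_alpha[i]
        carried <- if (rejected[i]) local_alpha[i] else 0
      }
      p_adj <- rep(NA_real_, m)
    },
    none = {
      p_adj <- p_raw
      local_alpha <- rep(alpha, m)
      rejected <- p_raw < alpha
    })
  data.frame(id = ids, p_raw = p_raw, p_adjusted = p_adj,
             local_alpha = local_alpha, tested = tested, rejected = rejected,
             stringsAsFactors = FALSE)
}

#' Exact closed-testing adjusted P-values by enumeration
#'
#' For each hypothesis the adjusted P-value is the maximum, over all
#' intersection hypotheses containing it, of the local test's P-value --
#' the definition of strong control under the closure principle, computed
#' by enumerating all `2^m - 1` subsets.  With Simes local tests this
#' equals Hommel's procedure; with Bonferroni local tests it equals
#' Holm's.  Intended as an independent oracle for small families.
#'
#' @param p_raw raw P-values (at most 12, since enumeration is `2^m`).
#' @param local_test `"simes"` or `"bonferroni"`.
#' @return adjusted P-values in input order, capped at 1.
#' @export
closed_testing_adjust <- function(p_raw, local_test = c("simes", "bonferroni")) {
  local_test <- match.arg(local_test)
  m <- length(p_raw)
  if (m < 1) stop("empty family", call. = FALSE)
  if (m > 12) stop("enumeration limited to m <= 12", call. = FALSE)
  local_p <- function(p) {
    k <- length(p)
    if (local_test == "simes") min(k * sort(p) / seq_len(k)) else k * min(p)
  }
  adj <- numeric(m)
  subsets <- seq_len(2^m - 1)
  subset_p <- vapply(subsets, function(s) {
    local_p(p_raw[bitwAnd(s, 2^(seq_len(m) - 1)) > 0])
  }, numeric(1))
  for (i in seq_len(m)) {
    contains_i <- bitwAnd(subsets, 2^(i - 1)) > 0
    adj[i] <- max(subset_p[contains_i])
  }
  pmin(adj, 1)
}
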