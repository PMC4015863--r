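#' Run the five-step assessment of a randomised trial
#'
#' Executes the five-step procedure over a validated trial specification:
#' (1) resolve and report confidence intervals and exact P-values for every
#' outcome with a result; (2) compute the Bayes factor of the primary
#' outcome against the sample-size-calculation alternative (plus any
#' additional alternatives and, when the anticipated effect is not based on
#' a systematic review, the sceptical alternative); (3) adjust the
#' significance threshold for early stopping or interim analyses; (4) apply
#' the multiplicity procedure across non-exploratory outcome comparisons;
#' (5) assess clinical significance, gated on steps 1-4 and a Bayes factor
#' below its threshold.  The report is deterministic given the
#' specification.
#'
#' @param spec a `"trial_spec"` from [read_trial_spec()] / [as_trial_spec()],
#'   or a path to a specification document.
#' @return an object of class `"trial_assessment"`: a list with `trial_name`,
#'   `outcomes` (resolved per-outcome table), `bf` (primary, additional and
#'   sceptical Bayes factors), and `steps`, a list of five records each
#'   holding `step`, `title`, `verdict` (`"pass"`, `"fail"`, `"warning"` or
#'   `"not_assessed"`), `values` and `notes`.
#' @examples
#' spec <- read_trial_spec(system.file("extdata", "example2.json",
#'                                     package = "fivestep"))
#' assess_trial(spec)
#' @export
assess_trial <- function(spec) {
  if (is.character(spec)) spec <- read_trial_spec(spec)
  stopifnot(inherits(spec, "trial_spec"))
  design <- spec$design

  ## ---- resolve outcomes -------------------------------------------------
  resolved <- list()
  unresolvable <- character(0)
  for (o in spec$outcomes) {
    if (is.null(o$result)) {
      resolved[[o$id]] <- list(id = o$id, role = o$role, has_result = FALSE)
      next
    }
    res <- tryCatch(resolve_outcome_result(o$result),
                    error = function(e) NULL)
    if (is.null(res)) {
      unresolvable <- c(unresolvable, o$id)
      next
    }
    res$id <- o$id; res$role <- o$role; res$has_result <- TRUE
    res$timepoints_assessed <- o$timepoints_assessed
    resolved[[o$id]] <- res
  }
  if (length(unresolvable))
    stop("cannot resolve effect inputs for outcome(s): ",
         paste(unresolvable, collapse = ", "), call. = FALSE)
  with_result <- Filter(function(r) isTRUE(r$has_result), resolved)
  if (length(with_result) == 0)
    stop("no outcome carries an observed result", call. = FALSE)

  primary_ids <- names(Filter(function(r)
    identical(r$role, "primary") && isTRUE(r$has_result), resolved))
  notes2 <- character(0)
  if (length(primary_ids) == 0) {
    primary_ids <- names(with_result)[1]
    notes2 <- "no outcome has the primary role; Bayes factor computed for the first reported outcome"
  }
  primary <- resolved[[primary_ids[1]]]

  ## ---- step 1: CIs and exact P-values -----------------------------------
  step1_tab <- lapply(with_result, function(r) {
    list(id = r$id, measure = r$measure,
         estimate = from_analysis_scale(r$theta, r$measure),
         theta = r$theta, se = r$se,
         ci_lower = if (r$scale == "log") exp(r$ci[1]) else r$ci[1],
         ci_upper = if (r$scale == "log") exp(r$ci[2]) else r$ci[2],
         p = r$p)
  })
  names(step1_tab) <- NULL
  step1 <- step_record(1, "Report the confidence intervals and the exact P-values",
                       verdict = "pass", values = list(outcomes = step1_tab),
                       notes = character(0))

  ## ---- step 2: Bayes factor ---------------------------------------------
  alt <- resolve_alternative(design$effect, design$control_risk)
  bf_primary <- bayes_factor(primary$theta, primary$se, alt$theta,
                             threshold = spec$bf_threshold)
  bf_additional <- list()
  if (!is.null(design$additional_alternatives)) {
    for (aa in design$additional_alternatives) {
      a2 <- resolve_alternative(aa, design$control_risk)
      bf_additional[[length(bf_additional) + 1]] <-
        bayes_factor(primary$theta, primary$se, a2$theta,
                     threshold = spec$bf_threshold)
    }
  }
  bf_sceptical <- NULL
  if (!isTRUE(design$effect_from_systematic_review) && !is.null(alt$ratio)) {
    sc <- sceptical_alternative(alt$ratio)
    bf_sceptical <- bayes_factor(primary$theta, primary$se, sc$theta,
                                 threshold = spec$bf_threshold)
    notes2 <- c(notes2,
      "anticipated effect not based on a systematic review; sceptical Bayes factor added")
  }
  step2_pass <- bf_primary$classification == "supports_alternative"
  step2 <- step_record(2, "Bayes factor for the primary outcome",
    verdict = if (step2_pass) "pass" else "fail",
    values = list(bf = bf_primary$bf, log_bf = bf_primary$log_bf,
                  theta_obs = bf_primary$theta_obs, se = bf_primary$se,
                  theta_alt = bf_primary$theta_alt,
                  classification = bf_primary$classification,
                  threshold = spec$bf_threshold,
                  bf_additional = vapply(bf_additional, function(b) b$bf,
                                         numeric(1)),
                  bf_sceptical = if (is.null(bf_sceptical)) NULL
                                 else bf_sceptical$bf),
    notes = notes2)

  ## ---- step 3: early stopping / interim adjustment ----------------------
  frac <- min(1, spec$n_randomised / design$planned_n_total)
  notes3 <- if (spec$n_randomised >= design$planned_n_total)
    "planned sample size reached" else
    sprintf("information fraction %.3f of the planned sample size", frac)
  seq_adj <- apply_sequential_adjustment(
    primary$p, frac, alpha = design$alpha,
    planned_fractions = spec$looks$planned_fractions,
    interim_looks_performed = spec$looks$interim_looks_performed)
  if (seq_adj$adjusted)
    notes3 <- c(notes3, sprintf(
      "threshold adjusted to %.4g (O'Brien-Fleming-type spending); report %.2f%% confidence intervals",
      seq_adj$required_threshold, 100 * seq_adj$adjusted_ci_level))
  step3 <- step_record(3, "Adjust thresholds if stopped early or after interim analyses",
    verdict = if (seq_adj$met) "pass" else "fail",
    values = list(information_fraction = frac,
                  interim_looks_performed = spec$looks$interim_looks_performed,
                  required_threshold = seq_adj$required_threshold,
                  adjusted_ci_level = seq_adj$adjusted_ci_level,
                  p_primary = primary$p),
    notes = notes3)

  ## ---- step 4: multiplicity ---------------------------------------------
  family <- Filter(function(r) !identical(r$role, "exploratory"), with_result)
  n_excluded <- length(with_result) - length(family)
  notes4 <- character(0)
  if (n_excluded > 0)
    notes4 <- sprintf(
      "%d exploratory comparison(s) excluded from the family; interpret their P-values conservatively",
      n_excluded)
  proc <- spec$multiplicity$procedure
  alpha_family <- spec$multiplicity$alpha_family
  n_comparisons <- sum(vapply(spec$outcomes, function(o)
    if (identical(o$role, "exploratory")) 0L
    else as.integer(if (is.null(o$timepoints_assessed)) 1 else o$timepoints_assessed),
    integer(1)))
  if (!spec$primary_predefined) {
    verdict4 <- "fail"
    notes4 <- c(notes4,
      "no clear definition of a primary outcome was pre-specified; the P-value should have been adjusted for multiplicity across the outcome comparisons")
    adj <- NULL
  } else if (length(family) <= 1 && n_comparisons <= 1) {
    verdict4 <- "pass"
    notes4 <- c(notes4,
      "a single pre-specified comparison at a single time point: no adjustment needed")
    adj <- NULL
  } else if (identical(proc, "none")) {
    verdict4 <- "warning"
    notes4 <- c(notes4, sprintf(
      "%d non-exploratory comparisons but no multiplicity procedure specified",
      max(length(family), n_comparisons)))
    adj <- NULL
  } else {
    adj <- adjust_family(vapply(family, function(r) r$p, numeric(1)),
                         procedure = proc, alpha = alpha_family,
                         weights = spec$multiplicity$weights,
                         ids = names(family))
    primary_row <- match(primary$id, adj$id)
    verdict4 <- if (isTRUE(adj$rejected[primary_row])) "pass" else "fail"
    notes4 <- c(notes4, sprintf("procedure: %s at family alpha %.4g",
                                proc, alpha_family))
  }
  step4 <- step_record(4, "Adjust for multiplicity of outcome comparisons",
    verdict = verdict4,
    values = list(procedure = proc, alpha_family = alpha_family,
                  n_comparisons = n_comparisons,
                  adjusted = if (is.null(adj)) NULL else adj),
    notes = notes4)

  ## ---- step 5: clinical significance ------------------------------------
  passed <- c(step1$verdict, step2$verdict, step3$verdict, step4$verdict) == "pass"
  gate <- clinical_gate(passed, bf_primary$bf, spec$bf_threshold)
  clin_values <- list(gate = gate)
  notes5 <- character(0)
  if (!is.null(primary$risk_control) && !is.null(primary$risk_experimental)) {
    dirb <- clinical_direction(spec, primary)
    nn <- nnt_nnh(primary$risk_control, primary$risk_experimental, dirb)
    clin_values$risk_difference <- primary$risk_experimental - primary$risk_control
    clin_values$nnt_nnh <- nn
    if (!gate)
      notes5 <- c(notes5, sprintf(
        "descriptive only (gate not met): %s %d from arm risks %.3f vs %.3f",
        nn$kind, nn$value, primary$risk_experimental, primary$risk_control))
  }
  if (gate && !is.null(spec$clinical) && !is.null(spec$clinical$mcid)) {
    mc <- compare_to_mcid(primary$theta, primary$ci[1], primary$ci[2],
                          spec$clinical$mcid)
    clin_values$mcid <- spec$clinical$mcid
    clin_values$mcid_met <- mc$mcid_met
    clin_values$ci_excludes_mcid_shortfall <- mc$ci_excludes_mcid_shortfall
  }
  if (gate) {
    notes5 <- c(notes5,
      "statistical significance obtained in steps 1-4 and Bayes factor below threshold; assess the balance between beneficial and harmful effects")
    verdict5 <- "pass"
  } else {
    notes5 <- c(notes5,
      "clinical significance not assessed: statistical significance was not obtained according to all of the first four steps with a Bayes factor below threshold")
    verdict5 <- "not_assessed"
  }
  step5 <- step_record(5, "Assess clinical significance", verdict = verdict5,
                       values = clin_values, notes = notes5)

  steps <- list(step1, step2, step3, step4, step5)
  overall <- overall_interpretation(steps, bf_primary)
  structure(list(trial_name = spec$trial_name,
                 outcomes = step1_tab,
                 bf = list(primary = bf_primary, additional = bf_additional,
                           sceptical = bf_sceptical),
                 steps = steps,
                 overall_interpretation = overall),
            class = "trial_assessment")
}

step_record <- function(step, title, verdict, values, notes) {
  list(step = step, title = title, verdict = verdict,
       values = values, notes = notes)
}

# resolve a result block (summary statistics or 2x2 counts) to the
# analysis-scale triplet; counts take the log-odds route
resolve_outcome_result <- function(r) {
  if (!is.null(r$events_experimental)) {
    tab <- two_by_two(r$events_experimental,
                      r$n_experimental - r$events_experimental,
                      r$events_control,
                      r$n_control - r$events_control)
    eff <- effects_from_table(tab)
    theta <- eff$log_or; se <- eff$se_log_or
    return(list(measure = "OR", scale = "log", theta = theta, se = se,
                p = p_from_estimate(theta, se),
                ci = theta + c(-1, 1) * stats::qnorm(0.975) * se,
                risk_control = eff$risk_control,
                risk_experimental = eff$risk_experimental,
                from_counts = TRUE))
  }
  est <- effect_estimate(
    measure = r$measure, point = r$estimate, log_estimate = r$log_estimate,
    ci_lower = r$ci_lower, ci_upper = r$ci_upper,
    ci_level = if (is.null(r$ci_level)) 0.95 else r$ci_level,
    se = r$se, p = r$p,
    direction_of_benefit = if (is.null(r$direction_of_benefit))
      "less_than_null" else r$direction_of_benefit)
  res <- resolve_estimate(est)
  res$from_counts <- FALSE
  res
}

# the alternative hypothesis on the log-odds (or mean-difference) scale,
# keeping the ratio-scale value for the sceptical midpoint
resolve_alternative <- function(effect, control_risk) {
  switch(effect$type,
    rr = {
      or <- rr_to_or(effect$value, control_risk)
      list(theta = log(or), ratio = or, type = "rr")
    },
    or = list(theta = log(effect$value), ratio = effect$value, type = "or"),
    log_or = list(theta = effect$value, ratio = exp(effect$value),
                  type = "log_or"),
    md = list(theta = effect$value, ratio = NULL, type = "md"),
    stop("unknown effect type", call. = FALSE))
}

clinical_direction <- function(spec, primary) {
  if (!is.null(spec$clinical) && !is.null(spec$clinical$direction_of_benefit))
    spec$clinical$direction_of_benefit
  else "less_than_null"
}

overall_interpretation <- function(steps, bf_primary) {
  verdicts <- vapply(steps, function(s) s$verdict, character(1))
  if (all(verdicts[1:4] == "pass") && verdicts[5] == "pass")
    "Statistical significance was reached according to all of the first four steps; clinical significance may be assessed."
  else if (bf_primary$classification == "supports_null")
    "The trial result is far more compatible with the null hypothesis than with the anticipated intervention effect; the intervention does not seem to have the hypothesised beneficial effect."
  else
    "Statistical significance was not adequately established across the five steps; the results should be interpreted with great caution and clinical significance is not assessed."
}
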