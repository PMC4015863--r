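#' Trial-specification documents
#'
#' A trial is described in a small JSON document (YAML is accepted as an
#' alternate dialect of the same schema): the design block carries the
#' sample-size calculation's ingredients, the outcomes block the observed
#' results and the outcome hierarchy, and optional blocks configure
#' interim looks, the multiplicity procedure and the clinical comparison.
#' Validation is schema-wide: every violation is reported with its path,
#' not just the first, and unknown fields are rejected.
#'
#' @name spec_io
NULL

.spec_schema <- list(
  top = c("trial_name", "design", "n_randomised", "looks", "outcomes",
          "primary_predefined", "multiplicity", "clinical",
          "bf_threshold", "p_threshold"),
  design = c("outcome_type", "control_risk", "effect", "sd", "alpha",
             "power", "planned_n_total", "allocation_ratio",
             "effect_from_systematic_review", "additional_alternatives"),
  effect = c("type", "value"),
  looks = c("planned_fractions", "interim_looks_performed"),
  outcome = c("id", "role", "result", "timepoints_assessed"),
  result = c("measure", "estimate", "log_estimate", "ci_lower", "ci_upper",
             "ci_level", "se", "p", "direction_of_benefit",
             "events_experimental", "n_experimental",
             "events_control", "n_control"),
  multiplicity = c("procedure", "alpha_family", "weights"),
  clinical = c("mcid", "mcid_scale", "direction_of_benefit")
)

#' Read and validate a trial specification
#'
#' @param path path to a `.json`, `.yaml` or `.yml` document, or a
#'   character string of raw JSON.
#' @return a validated object of class `"trial_spec"` with defaults filled
#'   in (`bf_threshold` 0.1, `p_threshold` 0.05, allocation ratio 1,
#'   `primary_predefined` TRUE, multiplicity procedure `"hommel"` when
#'   several non-exploratory outcomes exist and none is specified).
#' @examples
#' spec <- read_trial_spec(system.file("extdata", "example2.json",
#'                                     package = "fivestep"))
#' @export
read_trial_spec <- function(path) {
  doc <- if (length(path) == 1 && grepl("^\\s*\\{", path)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  as_trial_spec(doc)
}

#' Validate a trial-specification list
#'
#' @param doc a list with the document structure of [read_trial_spec()].
#' @return a `"trial_spec"` object.
#' @export
as_trial_spec <- function(doc) {
  errors <- character(0)
  fail <- function(path, msg) errors[length(errors) + 1] <<-
    sprintf("%s: %s", path, msg)
  check_keys <- function(x, allowed, path) {
    unknown <- setdiff(names(x), allowed)
    for (u in unknown) fail(paste0(path, "$", u), "unknown field")
  }
  if (!is.list(doc)) stop("specification must be a JSON/YAML object", call. = FALSE)
  check_keys(doc, .spec_schema$top, "spec")

  d <- doc$design
  if (is.null(d)) fail("spec$design", "required block is missing")
  else {
    check_keys(d, .spec_schema$design, "spec$design")
    if (is.null(d$effect)) fail("spec$design$effect", "required field is missing")
    else {
      check_keys(d$effect, .spec_schema$effect, "spec$design$effect")
      if (is.null(d$effect$type) ||
          !d$effect$type %in% c("rr", "or", "log_or", "md"))
        fail("spec$design$effect$type", "must be one of rr, or, log_or, md")
      if (is.null(d$effect$value) || !is.numeric(d$effect$value))
        fail("spec$design$effect$value", "must be numeric")
      else if (identical(d$effect$type, "rr") || identical(d$effect$type, "or")) {
        if (d$effect$value <= 0)
          fail("spec$design$effect$value", "ratio effects must be positive")
      }
    }
    if (!is.null(d$effect$type) && identical(d$effect$type, "rr") &&
        is.null(d$control_risk))
      fail("spec$design$control_risk", "required when the effect is a risk ratio")
    if (!is.null(d$control_risk) &&
        (d$control_risk <= 0 || d$control_risk >= 1))
      fail("spec$design$control_risk", "must be in (0, 1)")
    if (is.null(d$alpha)) d$alpha <- 0.05
    if (d$alpha <= 0 || d$alpha >= 1) fail("spec$design$alpha", "must be in (0, 1)")
    if (!is.null(d$power) && (d$power <= 0 || d$power >= 1))
      fail("spec$design$power", "must be in (0, 1)")
    if (is.null(d$planned_n_total) || d$planned_n_total <= 0)
      fail("spec$design$planned_n_total", "must be a positive integer")
    if (is.null(d$allocation_ratio)) d$allocation_ratio <- 1
    if (is.null(d$effect_from_systematic_review))
      d$effect_from_systematic_review <- FALSE
    if (!is.null(d$additional_alternatives)) {
      for (i in seq_along(d$additional_alternatives))
        check_keys(d$additional_alternatives[[i]], .spec_schema$effect,
                   sprintf("spec$design$additional_alternatives[[%d]]", i))
    }
  }

  if (is.null(doc$n_randomised) || doc$n_randomised <= 0)
    fail("spec$n_randomised", "must be a positive integer")

  looks <- doc$looks
  if (is.null(looks)) looks <- list()
  check_keys(looks, .spec_schema$looks, "spec$looks")
  if (is.null(looks$planned_fractions)) looks$planned_fractions <- numeric(0)
  looks$planned_fractions <- as.numeric(unlist(looks$planned_fractions))
  if (length(looks$planned_fractions) &&
      (any(looks$planned_fractions <= 0) || any(looks$planned_fractions > 1) ||
       any(diff(looks$planned_fractions) <= 0)))
    fail("spec$looks$planned_fractions",
         "must be strictly increasing fractions in (0, 1]")
  if (is.null(looks$interim_looks_performed)) looks$interim_looks_performed <- 0

  outcomes <- doc$outcomes
  if (is.null(outcomes) || length(outcomes) == 0)
    fail("spec$outcomes", "at least one outcome is required")
  else for (i in seq_along(outcomes)) {
    o <- outcomes[[i]]
    opath <- sprintf("spec$outcomes[[%d]]", i)
    check_keys(o, .spec_schema$outcome, opath)
    if (is.null(o$id)) fail(paste0(opath, "$id"), "required field is missing")
    if (is.null(o$role)) o$role <- "secondary"
    if (!o$role %in% c("primary", "secondary", "exploratory"))
      fail(paste0(opath, "$role"), "must be primary, secondary or exploratory")
    if (is.null(o$timepoints_assessed)) o$timepoints_assessed <- 1
    if (!is.null(o$result)) {
      check_keys(o$result, .spec_schema$result, paste0(opath, "$result"))
      r <- o$result
      has_counts <- !is.null(r$events_experimental)
      if (has_counts) {
        for (f in c("events_experimental", "n_experimental",
                    "events_control", "n_control"))
          if (is.null(r[[f]]))
            fail(paste0(opath, "$result$", f),
                 "all four count fields are required together")
      } else {
        if (is.null(r$measure)) fail(paste0(opath, "$result$measure"),
                                     "required for summary-statistic results")
        if (is.null(r$estimate) && is.null(r$log_estimate))
          fail(paste0(opath, "$result"),
               "an estimate or log_estimate is required")
        has_ci <- !is.null(r$ci_lower) && !is.null(r$ci_upper)
        if (!has_ci && is.null(r$se) && is.null(r$p))
          fail(paste0(opath, "$result"),
               "at least one of CI, se or p is required")
      }
    }
    outcomes[[i]] <- o
  }

  mult <- doc$multiplicity
  if (is.null(mult)) mult <- list()
  check_keys(mult, .spec_schema$multiplicity, "spec$multiplicity")
  if (!is.null(mult$procedure) &&
      !mult$procedure %in% c("hommel", "bonferroni", "fixed_sequence",
                             "fallback", "none"))
    fail("spec$multiplicity$procedure", "unknown procedure")

  clin <- doc$clinical
  if (!is.null(clin)) check_keys(clin, .spec_schema$clinical, "spec$clinical")

  if (length(errors))
    stop("invalid trial specification:\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)

  spec <- list(
    trial_name = if (is.null(doc$trial_name)) "unnamed trial" else doc$trial_name,
    design = d,
    n_randomised = doc$n_randomised,
    looks = looks,
    outcomes = outcomes,
    primary_predefined = if (is.null(doc$primary_predefined)) TRUE
                         else isTRUE(doc$primary_predefined),
    multiplicity = mult,
    clinical = clin,
    bf_threshold = if (is.null(doc$bf_threshold)) 0.1 else doc$bf_threshold,
    p_threshold = if (is.null(doc$p_threshold)) 0.05 else doc$p_threshold
  )
  non_expl <- sum(vapply(spec$outcomes,
                         function(o) !identical(o$role, "exploratory"),
                         logical(1)))
  if (is.null(spec$multiplicity$procedure))
    spec$multiplicity$procedure <- if (non_expl > 1) "hommel" else "none"
  if (is.null(spec$multiplicity$alpha_family))
    spec$multiplicity$alpha_family <- spec$design$alpha
  structure(spec, class = "trial_spec")
}

#' Write a validated trial specification back to JSON
#'
#' @param spec a `"trial_spec"` object.
#' @param path output file path.
#' @return `path`, invisibly.  `read_trial_spec(write_trial_spec(spec, p))`
#'   is the identity on validated objects.
#' @export
write_trial_spec <- function(spec, path) {
  stopifnot(inherits(spec, "trial_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
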