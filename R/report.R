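#' Render an assessment report
#'
#' `"json"` gives a schema-stable, machine-diffable document (byte-identical
#' for identical specifications); `"markdown"` mirrors the five-point
#' layout of a written assessment, with log effects displayed to two
#' decimals and standard errors to three.
#'
#' @param report a `"trial_assessment"` from [assess_trial()].
#' @param format `"json"` or `"markdown"`.
#' @return a single character string.
#' @export
render_report <- function(report, format = c("json", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "trial_assessment"))
  if (format == "json") {
    doc <- list(
      trial_name = report$trial_name,
      overall_interpretation = report$overall_interpretation,
      bayes_factor = list(
        primary = bf_fields(report$bf$primary),
        additional = lapply(report$bf$additional, bf_fields),
        sceptical = if (is.null(report$bf$sceptical)) NULL
                    else bf_fields(report$bf$sceptical)),
      steps = lapply(report$steps, function(s)
        list(step = s$step, title = s$title, verdict = s$verdict,
             values = s$values, notes = as.list(s$notes))))
    as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = 10,
                                  pretty = TRUE, null = "null"))
  } else {
    render_markdown(report)
  }
}

bf_fields <- function(b) {
  list(bf = b$bf, log_bf = b$log_bf, theta_obs = b$theta_obs, se = b$se,
       theta_alt = b$theta_alt, threshold = b$threshold,
       classification = b$classification)
}

bf_display <- function(bf) {
  if (bf >= 1000) formatC(round(bf), format = "d", big.mark = ",")
  else sprintf("%.2f", bf)
}

render_markdown <- function(report) {
  lines <- c(sprintf("# Five-step assessment: %s", report$trial_name), "")
  tick <- c(pass = "pass", fail = "FAIL", warning = "WARNING",
            not_assessed = "not assessed")
  for (s in report$steps) {
    lines <- c(lines, sprintf("## Step %d. %s  [%s]", s$step, s$title,
                              tick[[s$verdict]]), "")
    lines <- c(lines, step_lines(s, report), "")
    for (n in s$notes) lines <- c(lines, sprintf("- %s", n))
    if (length(s$notes)) lines <- c(lines, "")
  }
  lines <- c(lines, "## Interpretation", "", report$overall_interpretation, "")
  paste(lines, collapse = "\n")
}

step_lines <- function(s, report) {
  v <- s$values
  switch(as.character(s$step),
    "1" = vapply(v$outcomes, function(o) sprintf(
      "- %s: %s %.2f (%.0f%% CI %.2f to %.2f), P = %.4g",
      o$id, o$measure, o$estimate, 95, o$ci_lower, o$ci_upper, o$p),
      character(1)),
    "2" = {
      out <- sprintf(
        "- log odds ratio %.2f (SE %.3f) against alternative %.2f: Bayes factor = %s (%s)",
        v$theta_obs, v$se, v$theta_alt, bf_display(v$bf),
        gsub("_", " ", v$classification))
      if (length(v$bf_additional))
        out <- c(out, sprintf("- additional alternative: Bayes factor = %s",
                              vapply(v$bf_additional, bf_display, character(1))))
      if (!is.null(v$bf_sceptical))
        out <- c(out, sprintf("- sceptical alternative: Bayes factor = %s",
                              bf_display(v$bf_sceptical)))
      out
    },
    "3" = sprintf(
      "- information fraction %.3f; required threshold %.4g; observed P = %.4g (%s)",
      v$information_fraction, v$required_threshold, v$p_primary,
      if (v$p_primary < v$required_threshold) "met" else "not met"),
    "4" = sprintf("- procedure: %s; %d outcome comparison(s) at family alpha %.4g",
                  v$procedure, v$n_comparisons, v$alpha_family),
    "5" = {
      out <- character(0)
      if (!is.null(v$nnt_nnh))
        out <- c(out, sprintf("- %s = %d (risk difference %.3f)",
                              v$nnt_nnh$kind, v$nnt_nnh$value,
                              v$risk_difference))
      if (!is.null(v$mcid_met))
        out <- c(out, sprintf("- minimal clinically relevant difference %s met%s",
                              if (v$mcid_met) "" else "not",
                              if (isTRUE(v$ci_excludes_mcid_shortfall))
                                " (whole CI beyond the MCID)" else ""))
      if (!length(out)) out <- sprintf("- gate %s", if (v$gate) "met" else "not met")
      out
    })
}

#' @export
print.trial_assessment <- function(x, ...) {
  cat(sprintf("Five-step assessment of '%s'\n", x$trial_name))
  for (s in x$steps)
    cat(sprintf("  step %d [%-12s] %s\n", s$step, s$verdict, s$title))
  cat(sprintf("  Bayes factor (primary): %s\n", bf_display(x$bf$primary$bf)))
  cat("  ", x$overall_interpretation, "\n", sep = "")
  invisible(x)
}

#' @export
summary.trial_assessment <- function(object, ...) {
  cat(render_report(object, "markdown"))
  invisible(object)
}
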