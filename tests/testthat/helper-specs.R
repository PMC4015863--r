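# example trial specifications, built in code so tests do not depend on the
# installed extdata copies (which are separately checked against these)

example_spec <- function(which) {
  path <- system.file("extdata", sprintf("example%d.json", which),
                      package = "fivestep")
  read_trial_spec(path)
}

# a minimal well-formed specification used as a template for edge cases
minimal_spec_list <- function() {
  list(
    trial_name = "toy trial",
    design = list(outcome_type = "binary", control_risk = 0.5,
                  effect = list(type = "rr", value = 0.8),
                  alpha = 0.05, power = 0.8, planned_n_total = 800,
                  effect_from_systematic_review = TRUE),
    n_randomised = 800,
    outcomes = list(list(id = "death", role = "primary",
                         result = list(measure = "OR", log_estimate = -0.5,
                                       se = 0.15)))
  )
}

verdicts <- function(assessment) {
  vapply(assessment$steps, function(s) s$verdict, character(1))
}
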