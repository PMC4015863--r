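test_that("specification validation collects all violations with paths", {
  bad <- minimal_spec_list()
  bad$design$effect$type <- "hazard"
  bad$outcomes <- list()
  bad$typo_field <- 1
  err <- tryCatch(as_trial_spec(bad), error = function(e) conditionMessage(e))
  expect_match(err, "spec\\$design\\$effect\\$type")
  expect_match(err, "spec\\$outcomes")
  expect_match(err, "spec\\$typo_field.*unknown field")
})

test_that("unknown nested fields are rejected with precise paths", {
  bad <- minimal_spec_list()
  bad$outcomes[[1]]$result$standard_error <- 0.1
  expect_error(as_trial_spec(bad),
               "outcomes\\[\\[1\\]\\]\\$result\\$standard_error")
})

test_that("defaults are filled: Hommel for several undifferentiated comparisons", {
  doc <- minimal_spec_list()
  doc$outcomes[[2]] <- list(id = "qol", role = "secondary",
                            result = list(measure = "MD", estimate = 1.2,
                                          se = 0.4))
  spec <- as_trial_spec(doc)
  expect_equal(spec$multiplicity$procedure, "hommel")
  expect_equal(spec$bf_threshold, 0.1)
  single <- as_trial_spec(minimal_spec_list())
  expect_equal(single$multiplicity$procedure, "none")
})

test_that("write -> read round trip is the identity on validated objects", {
  spec <- as_trial_spec(minimal_spec_list())
  path <- tempfile(fileext = ".json")
  write_trial_spec(spec, path)
  spec2 <- read_trial_spec(path)
  expect_equal(spec2, spec)
})

test_that("YAML is accepted as an alternate dialect of the same schema", {
  spec <- as_trial_spec(minimal_spec_list())
  ypath <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(spec), ypath)
  spec_y <- read_trial_spec(ypath)
  expect_equal(verdicts(assess_trial(spec_y)), verdicts(assess_trial(spec)))
})

test_that("assessment is deterministic and JSON rendering idempotent", {
  spec <- example_spec(2)
  a1 <- assess_trial(spec)
  a2 <- assess_trial(spec)
  expect_identical(render_report(a1, "json"), render_report(a2, "json"))
  expect_identical(render_report(a1, "markdown"), render_report(a2, "markdown"))
})

test_that("the markdown report shows the rounded Bayes factor and gate explanation", {
  md2 <- render_report(assess_trial(example_spec(2)), "markdown")
  expect_match(md2, "Bayes factor = 0.01", fixed = TRUE)
  md3 <- render_report(assess_trial(example_spec(3)), "markdown")
  expect_match(md3, "not assessed")
  expect_match(md3, "clinical significance not assessed", ignore.case = TRUE)
  expect_match(md3, "NNH = 13", fixed = TRUE)
})

test_that("unresolvable outcomes produce a validation error naming them", {
  doc <- minimal_spec_list()
  doc$outcomes[[1]]$result <- list(measure = "OR", estimate = 0.8, p = 1)
  spec <- as_trial_spec(doc)
  expect_error(assess_trial(spec), "death")
})

test_that("verdicts are monotone: a worse P or BF never flips fail to pass", {
  doc <- minimal_spec_list()
  base <- verdicts(assess_trial(as_trial_spec(doc)))
  worse <- doc
  worse$outcomes[[1]]$result$log_estimate <- -0.05  # weaker effect
  vw <- verdicts(assess_trial(as_trial_spec(worse)))
  rank <- c(pass = 0, warning = 1, fail = 2, not_assessed = 2)
  expect_true(all(rank[vw] >= rank[base]))
})

test_that("a missing primary role triggers the fallback note, not an error", {
  doc <- minimal_spec_list()
  doc$outcomes[[1]]$role <- "secondary"
  a <- assess_trial(as_trial_spec(doc))
  expect_match(paste(a$steps[[2]]$notes, collapse = " "), "primary role")
})

test_that("interim looks lower the step-3 threshold enough to flip a marginal P", {
  doc <- minimal_spec_list()
  doc$outcomes[[1]]$result <- list(measure = "OR", estimate = 0.85, p = 0.04)
  doc$n_randomised <- 400   # stopped at half the planned 800
  a <- assess_trial(as_trial_spec(doc))
  expect_equal(a$steps[[3]]$verdict, "fail")
  expect_lt(a$steps[[3]]$values$required_threshold, 0.006)
})
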