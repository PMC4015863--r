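test_that("analysis-scale transform is log for ratios, identity for MD, and invertible", {
  expect_equal(to_analysis_scale(0.92, measure = "OR")$value, log(0.92))
  expect_equal(to_analysis_scale(1.0, measure = "OR")$value, 0)
  expect_equal(to_analysis_scale(1.35, measure = "RR")$value, log(1.35))
  expect_equal(to_analysis_scale(-2.3, measure = "MD")$value, -2.3)
  expect_equal(to_analysis_scale(-2.3, measure = "MD")$scale, "identity")
  for (x in c(0.1, 0.92, 1, 4.7))
    expect_equal(from_analysis_scale(to_analysis_scale(x, measure = "HR")$value,
                                     "HR"), x)
  expect_error(to_analysis_scale(-1, measure = "OR"), "positive")
})

test_that("published display values round-trip through the conversions", {
  # hazard ratio 0.92 with CI 0.86-0.998: log -0.08, SE 0.04 at display precision
  expect_equal(round(log(0.92), 2), -0.08)
  expect_equal(round(se_from_ci(0.86, 0.998), 2), 0.04)
  expect_equal(se_from_ci(0.86, 0.998), 0.03796521, tolerance = 1e-6)
  expect_equal(round(log(1.35), 2), 0.30)
})

test_that("se_from_ci matches the closed form and rejects bad input", {
  expect_equal(se_from_ci(exp(-qnorm(0.975)), exp(qnorm(0.975))), 1.0)
  expect_equal(se_from_ci(1.01, 1.36), 0.07590302, tolerance = 1e-6)
  expect_equal(se_from_ci(-1, 1, scale = "identity"),
               1 / qnorm(0.975))
  expect_error(se_from_ci(1.2, 0.8), "ordered")
  expect_error(se_from_ci(-0.1, 1.2, scale = "log"), "positive")
  expect_error(se_from_ci(0.8, 1.2, ci_level = 1.2), "ci_level")
})

test_that("Wald P and SE are mutual inverses", {
  expect_equal(p_from_estimate(0, 0.3), 1.0)
  expect_equal(p_from_estimate(-0.12, 0.04), 2 * pnorm(-3))
  expect_equal(p_from_estimate(qnorm(0.975) * 0.7, 0.7), 0.05)
  expect_equal(se_from_p(-0.0834, 0.04), 0.04060866, tolerance = 1e-6)
  expect_equal(se_from_p(qnorm(0.975), 0.05), 1.0)
  set.seed(41)
  for (i in 1:50) {
    theta <- rnorm(1); se <- rexp(1) + 0.01
    z <- abs(theta) / se
    if (z < 1e-4 || z > 6) next  # P ~ 1 or deep in the tail
    # double precision through the normal tail limits the round trip to ~1e-9
    expect_equal(se_from_p(theta, p_from_estimate(theta, se)), se,
                 tolerance = 1e-8)
  }
  expect_error(se_from_p(0, 0.05), "null estimate")
  expect_error(se_from_p(0.5, 1), "0, 1")
})

test_that("CI excludes the null exactly when the Wald P is below 1 - level", {
  set.seed(42)
  for (i in 1:200) {
    theta <- rnorm(1, sd = 0.5); se <- rexp(1, 5) + 0.01
    level <- sample(c(0.9, 0.95, 0.99), 1)
    ci <- ci_from_se(theta, se, level, scale = "identity")
    excludes <- ci[1] > 0 || ci[2] < 0
    expect_equal(excludes, p_from_estimate(theta, se) < (1 - level))
  }
})

test_that("2x2 effect measures match the closed formulas", {
  eff <- effects_from_table(two_by_two(202, 194, 173, 229))
  expect_equal(eff$se_log_or, 0.1423106, tolerance = 1e-6)
  expect_equal(round(eff$se_log_or, 3), 0.142)
  expect_equal(eff$or, 202 * 229 / (194 * 173))
  expect_equal(eff$risk_experimental, 202 / 396)
  expect_equal(eff$risk_control, 173 / 402)
  expect_false(eff$continuity_corrected)

  sym <- effects_from_table(two_by_two(10, 10, 10, 10))
  expect_equal(sym$or, 1.0)
  expect_equal(sym$risk_difference, 0.0)

  corr <- effects_from_table(two_by_two(1, 0, 1, 1))
  expect_true(corr$continuity_corrected)
  expect_true(all(is.finite(unlist(corr[c("or", "log_or", "se_log_or")]))))
  expect_error(two_by_two(0, 0, 1, 1), "at least one participant")
})

test_that("rr_to_or matches the odds algebra and its limiting table", {
  expect_equal(rr_to_or(0.90, 0.20), 0.8780488, tolerance = 1e-7)
  expect_equal(rr_to_or(1.0, 0.37), 1.0)
  expect_equal(rr_to_or(0.80, 0.50), (0.4 / 0.6) / (0.5 / 0.5))
  # OR of the exact large-n table built from (p0, rr*p0) equals rr_to_or
  n <- 1e6
  for (pars in list(c(0.9, 0.2), c(1.3, 0.4), c(0.5, 0.1))) {
    rr <- pars[1]; p0 <- pars[2]; p1 <- rr * p0
    tab <- two_by_two(round(p1 * n), n - round(p1 * n),
                      round(p0 * n), n - round(p0 * n))
    expect_equal(effects_from_table(tab)$or, rr_to_or(rr, p0),
                 tolerance = 1e-9)
  }
  expect_error(rr_to_or(3, 0.5), "must be < 1")
})

test_that("estimate resolution prefers the CI and flags large CI/P disagreement", {
  est <- effect_estimate("HR", 0.92, ci_lower = 0.86, ci_upper = 0.998,
                         p = 0.04)
  r <- resolve_estimate(est)
  expect_equal(r$se_source, "ci")
  expect_equal(r$se, se_from_ci(0.86, 0.998))
  expect_equal(r$p, 0.04)     # supplied exact P is reported as-is

  disagreeing <- effect_estimate("OR", 0.92, ci_lower = 0.86,
                                 ci_upper = 0.998, p = 0.2)
  expect_warning(resolve_estimate(disagreeing), "disagree")

  from_p <- resolve_estimate(effect_estimate("OR", 0.8, p = 0.01))
  expect_equal(from_p$se_source, "p")
  expect_equal(p_from_estimate(from_p$theta, from_p$se), 0.01)

  expect_error(effect_estimate("OR", 0.8), "at least one of")
  expect_error(effect_estimate("OR", 0.9, ci_lower = 0.95, ci_upper = 1.2),
               "bracket")
})
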