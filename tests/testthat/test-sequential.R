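test_that("the OBF spending function spends alpha as designed", {
  expect_equal(obf_spending(1, 0.05), 0.05)
  expect_equal(obf_spending(0.5, 0.05),
               2 * pnorm(-qnorm(0.975) / sqrt(0.5)), tolerance = 1e-12)
  expect_equal(obf_spending(0.5, 0.05), 0.005574597, tolerance = 1e-7)
  expect_lt(obf_spending(1e-4, 0.05), 1e-12)   # vanishing early spend
  ts <- seq(0.05, 1, 0.05)
  expect_true(all(diff(obf_spending(ts, 0.05)) > 0))
  expect_error(obf_spending(0, 0.05), "positive")
})

test_that("a single look at full information reduces to the fixed design", {
  b <- gs_boundaries(1, 0.05)
  expect_equal(b$z_boundary, qnorm(0.975), tolerance = 1e-8)
  expect_equal(b$nominal_p, 0.05, tolerance = 1e-8)
  expect_equal(b$cumulative_alpha_spent, 0.05, tolerance = 1e-8)
})

test_that("classic two-look OBF boundaries match the literature values", {
  b <- gs_boundaries(c(0.5, 1), method = "obf_classic")
  expect_equal(b$z_boundary, c(2.7965, 1.9774), tolerance = 2e-4)
  expect_true(all(diff(b$z_boundary) < 0))
})

test_that("cumulative spent alpha is conserved and monotone for both methods", {
  for (method in c("obf_spending", "obf_classic")) {
    for (fr in list(c(0.5, 1), c(0.25, 0.5, 0.75, 1), seq(0.2, 1, 0.2))) {
      b <- gs_boundaries(fr, 0.05, method = method)
      expect_equal(b$cumulative_alpha_spent[length(fr)], 0.05,
                   tolerance = 1e-6)
      expect_true(all(diff(b$cumulative_alpha_spent) > 0))
      expect_true(all(diff(b$z_boundary) < 0))   # OBF boundaries shrink
    }
  }
})

test_that("spending-function boundaries track the classic form at equal spacing", {
  # the Lan-DeMets OBF-type function approximates (not equals) the classic
  # boundary; the final critical values are close, early looks less so
  for (K in 2:5) {
    fr <- seq_len(K) / K
    zs <- gs_boundaries(fr, 0.05, "obf_spending")$z_boundary
    zc <- gs_boundaries(fr, 0.05, "obf_classic")$z_boundary
    expect_lt(abs(zs[K] - zc[K]), 0.05)
    expect_lt(max(abs(zs - zc)), 0.2)
  }
})

test_that("two-look crossing probabilities match a large Monte-Carlo oracle", {
  b <- gs_boundaries(c(0.5, 1), method = "obf_classic")
  sim <- simulate_sequential_rejection(c(0.5, 1), b$z_boundary,
                                       replicates = 1e6, seed = 2024)
  expect_lt(abs(sim$rejection_rate - 0.05), 3 * sim$mc_se)
})

test_that("adjusted CI level is the complement of the nominal threshold", {
  expect_equal(adjusted_ci_level(0.05), 0.95)
  expect_equal(adjusted_ci_level(0.005574597), 0.9944254)
  for (t in c(0.2, 0.5, 0.9))
    expect_gt(adjusted_ci_level(obf_spending(t, 0.05)), 0.95)
  expect_error(adjusted_ci_level(0), "0, 1")
})

test_that("step-3 adjustment keeps full-information trials unchanged and penalises early stops", {
  full <- apply_sequential_adjustment(0.0035, 1)
  expect_equal(full$required_threshold, 0.05)
  expect_false(full$adjusted)
  expect_true(full$met)

  early <- apply_sequential_adjustment(0.04, 0.5)
  expect_equal(early$required_threshold, obf_spending(0.5, 0.05))
  expect_false(early$met)
  expect_gt(early$adjusted_ci_level, 0.99)

  # planned interim schedule: threshold comes from the boundary set
  sched <- apply_sequential_adjustment(0.001, 0.5, planned_fractions = c(0.5, 1),
                                       interim_looks_performed = 1)
  b <- gs_boundaries(0.5, 0.05)
  expect_equal(sched$required_threshold, b$nominal_p[1], tolerance = 1e-9)
  expect_true(sched$met)
})

test_that("boundary schedules reject malformed input", {
  expect_error(gs_boundaries(c(0.5, 0.4)), "strictly increasing")
  expect_error(gs_boundaries(c(0.5, 1.2)), "strictly increasing")
  expect_error(gs_boundaries(numeric(0)), "at least one look")
})
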