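test_that("Bonferroni multiplies, caps at 1, and leaves singletons alone", {
  a <- adjust_family(c(0.01, 0.4, 0.02, 0.3, 0.05), "bonferroni")
  expect_equal(a$p_adjusted, pmin(1, 5 * c(0.01, 0.4, 0.02, 0.3, 0.05)))
  expect_equal(a$local_alpha, rep(0.01, 5))
  expect_equal(adjust_family(0.03, "bonferroni")$p_adjusted, 0.03)
  expect_equal(adjust_family(c(0.4, 0.3, 0.35, 0.3, 0.25), "bonferroni")$p_adjusted,
               rep(1, 5))
})

test_that("Hommel reproduces hand-worked closed-testing values", {
  expect_equal(adjust_family(c(0.01, 0.50), "hommel")$p_adjusted, c(0.02, 0.50))
  expect_equal(adjust_family(c(0.04, 0.04, 0.04), "hommel")$p_adjusted,
               rep(0.04, 3))
  expect_equal(adjust_family(0.04, "hommel")$p_adjusted, 0.04)
})

test_that("Hommel equals the exhaustive closed-testing/Simes oracle", {
  set.seed(99)
  for (i in 1:300) {
    m <- sample(1:5, 1)
    p <- runif(m)^sample(1:3, 1) # skew some families towards small p
    expect_equal(adjust_family(p, "hommel")$p_adjusted,
                 closed_testing_adjust(p, "simes"), tolerance = 1e-12)
  }
})

test_that("closed testing with Bonferroni local tests equals Holm", {
  set.seed(98)
  for (i in 1:100) {
    m <- sample(1:5, 1)
    p <- runif(m)
    expect_equal(closed_testing_adjust(p, "bonferroni"),
                 p.adjust(p, "holm"), tolerance = 1e-12)
  }
  expect_equal(closed_testing_adjust(0.2), 0.2)
  expect_error(closed_testing_adjust(runif(13)), "m <= 12")
})

test_that("Hommel is never more conservative than Bonferroni, both never below raw", {
  set.seed(97)
  for (i in 1:100) {
    p <- runif(sample(1:6, 1))
    hom <- adjust_family(p, "hommel")$p_adjusted
    bon <- adjust_family(p, "bonferroni")$p_adjusted
    expect_true(all(hom <= bon + 1e-12))
    expect_true(all(hom >= p - 1e-12))
  }
})

test_that("Bonferroni and Hommel are permutation-equivariant", {
  set.seed(96)
  p <- runif(5)
  perm <- sample(5)
  for (proc in c("bonferroni", "hommel")) {
    a <- adjust_family(p, proc)$p_adjusted
    b <- adjust_family(p[perm], proc)$p_adjusted
    expect_equal(b, a[perm])
  }
})

test_that("fixed-sequence testing stops at the first failure", {
  a <- adjust_family(c(0.01, 0.04, 0.20, 0.03), "fixed_sequence")
  expect_equal(a$rejected, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(a$tested, c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(adjust_family(rep(0.01, 4), "fixed_sequence")$rejected))
  none <- adjust_family(c(0.06, 0.001), "fixed_sequence")
  expect_equal(none$rejected, c(FALSE, FALSE))
  expect_equal(none$tested, c(TRUE, FALSE))
})

test_that("fallback accumulates alpha along the hierarchy and never stops", {
  a <- adjust_family(c(0.01, 0.04), "fallback", weights = c(0.5, 0.5))
  expect_equal(a$local_alpha, c(0.025, 0.05))
  expect_true(all(a$rejected))
  b <- adjust_family(c(0.03, 0.04), "fallback", weights = c(0.5, 0.5))
  expect_equal(b$local_alpha, c(0.025, 0.025))
  expect_false(any(b$rejected))
  expect_true(all(b$tested))
  # weights (1, 0) reproduce fixed-sequence decisions on two hypotheses
  set.seed(95)
  for (i in 1:50) {
    p <- runif(2, 0, 0.12)
    expect_equal(adjust_family(p, "fallback", weights = c(1, 0))$rejected,
                 adjust_family(p, "fixed_sequence")$rejected)
  }
  expect_error(adjust_family(c(0.1, 0.1), "fallback", weights = c(0.5, 0.4)),
               "sum to 1")
})

test_that("every procedure controls the FWER strongly in simulation", {
  reps <- 1e4
  m <- 4
  run_fwer <- function(theta) { # theta: per-hypothesis true effects
    set.seed(555)
    true_null <- theta == 0
    fwer <- sapply(c("bonferroni", "hommel", "fixed_sequence", "fallback"),
      function(proc) {
        set.seed(555)
        z <- matrix(rnorm(reps * m), reps, m) +
          matrix(theta, reps, m, byrow = TRUE)
        p <- 2 * pnorm(-abs(z))
        any_false_rej <- vapply(seq_len(reps), function(r) {
          adj <- adjust_family(p[r, ], proc,
                               weights = if (proc == "fallback")
                                 rep(1 / m, m) else NULL)
          any(adj$rejected[true_null])
        }, logical(1))
        mean(any_false_rej)
      })
    fwer
  }
  mc3 <- 3 * sqrt(0.05 * 0.95 / reps)
  expect_true(all(run_fwer(rep(0, m)) <= 0.05 + mc3))       # global null
  expect_true(all(run_fwer(c(5, 5, 0, 0)) <= 0.05 + mc3))   # half null
})

test_that("degenerate families are rejected", {
  expect_error(adjust_family(numeric(0)), "empty")
  expect_error(adjust_family(c(0.5, 1.2)), "0, 1")
  expect_error(adjust_family(c(0.1, 0.1), "fallback"), "one weight")
})
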