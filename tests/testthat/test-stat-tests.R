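test_that("permutation test gives p = 1 when nothing exceeds zero difference", {
  res <- dse_permutation_pvalue(c(1, 2), c(1, 2), nperm = 200, seed = 1)
  expect_identical(res$statistic, 0)
  expect_identical(res$p.value, 1)
})

test_that("permutation test is deterministic given a seed and swap-invariant", {
  set.seed(21)
  a <- rlnorm(7)
  b <- rlnorm(12)
  r1 <- dse_permutation_pvalue(a, b, nperm = 500, seed = 42)
  r2 <- dse_permutation_pvalue(a, b, nperm = 500, seed = 42)
  expect_identical(r1, r2)
  r3 <- dse_permutation_pvalue(b, a, nperm = 500, seed = 42)
  expect_identical(r1$p.value, r3$p.value)
  # sample order within a condition is irrelevant
  r4 <- dse_permutation_pvalue(rev(a), sample(b), nperm = 500, seed = 42)
  expect_identical(r1$p.value, r4$p.value)
})

test_that("sampled permutation p agrees with exhaustive enumeration", {
  p_exact <- exact_perm_p(c(1, 1), c(1, 9))
  res <- dse_permutation_pvalue(c(1, 1), c(1, 9), nperm = 4000, seed = 7)
  se3 <- 3 * sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lte(abs(res$p.value - p_exact), se3 + 1 / 4000)
})

test_that("bias-corrected estimator can never return zero", {
  set.seed(22)
  a <- c(1, 100, 1)
  b <- c(50, 50, 50)
  res <- dse_permutation_pvalue(a, b, nperm = 50, seed = 3,
                                bias_correct = TRUE)
  expect_gt(res$p.value, 0)
  expect_lte(res$p.value, 1)
})

test_that("permutation test validates its inputs", {
  expect_error(dse_permutation_pvalue(c(1, -1), c(1, 2)), "non-positive")
  expect_error(dse_permutation_pvalue(c(1, 2), c(1, 2), nperm = 0),
               "positive integer")
  expect_error(dse_permutation_pvalue(2, c(1, 2)), "at least 2")
})

test_that("Fligner-Killeen matches the hand-coded rank/normal-score oracle", {
  cases <- list(
    list(a = c(1.2, 3.4, 2.2, 8.1, 0.7), b = c(2.0, 2.1, 2.3, 1.9, 2.2, 2.05)),
    list(a = exp(c(0.1, 0.9, 0.4, 0.6)), b = exp(c(2, 2.5, 1.1, 3, 2.2))),
    list(a = c(5, 6, 7, 8, 9, 10), b = c(1, 100, 2, 50))
  )
  for (cs in cases) {
    got <- fligner_killeen_pvalue(cs$a, cs$b)
    want <- fk_oracle(cs$a, cs$b)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
    expect_equal(got$p.value, want$p.value, tolerance = 1e-9)
  }
})

test_that("Fligner-Killeen is invariant to the log base and to identical groups", {
  a <- c(1.5, 2.5, 9, 4)
  b <- c(2, 8, 3, 7, 5)
  nat <- fligner_killeen_pvalue(a, b)
  base2 <- fk_oracle(a, b, logfun = log2)
  expect_equal(nat$statistic, base2$statistic, tolerance = 1e-9)
  same <- fligner_killeen_pvalue(a, a)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p.value, 1, tolerance = 1e-12)
})

test_that("Fligner-Killeen degenerate all-constant case warns and returns 1", {
  expect_warning(res <- fligner_killeen_pvalue(c(2, 2, 2), c(5, 5, 5)),
                 "undefined")
  expect_identical(res$p.value, 1)
})

test_that("Welch t-test is two-sided, symmetric, and handles degeneracy", {
  expect_identical(de_ttest_pvalue(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  set.seed(23)
  a <- rnorm(8, 5)
  b <- rnorm(5, 7)
  expect_identical(de_ttest_pvalue(a, b)$p.value,
                   de_ttest_pvalue(b, a)$p.value)
  # agrees with the standard Welch computation
  expect_equal(de_ttest_pvalue(a, b)$p.value, t.test(a, b)$p.value)
  expect_warning(r1 <- de_ttest_pvalue(c(4, 4), c(4, 4)), "equal")
  expect_identical(r1$p.value, 1)
  expect_warning(r0 <- de_ttest_pvalue(c(4, 4), c(5, 5)), "different")
  expect_identical(r0$p.value, 0)
})

test_that("p-value adjustment matches hand-worked examples", {
  expect_equal(adjust_pvalues(c(0.01, 0.04), "bonferroni"), c(0.02, 0.08))
  # step-up: sorted p_i * m / i all equal 0.04, cumulative minima 0.04
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  for (m in c("bonferroni", "holm", "hochberg", "bh", "by")) {
    expect_equal(adjust_pvalues(0.03, m), 0.03)
  }
  expect_equal(adjust_pvalues(c(0.5, NA, 0.01), "bonferroni"),
               c(1, NA, 0.02))
})

test_that("adjustment agrees with independently coded procedures", {
  set.seed(24)
  oracles <- list(bonferroni = bonferroni_oracle, holm = holm_oracle,
                  hochberg = hochberg_oracle, bh = bh_oracle,
                  by = by_oracle)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    for (m in names(oracles)) {
      adj <- adjust_pvalues(p, m)
      expect_equal(adj, oracles[[m]](p), tolerance = 1e-12,
                   info = paste("method", m))
      expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
    }
  }
})

test_that("unknown adjustment methods are rejected with the valid list", {
  expect_error(adjust_pvalues(c(0.1), "hommel"),
               "bonferroni, holm, hochberg, bh, by")
  expect_error(adjust_pvalues(c(1.2), "bh"), "\\[0, 1\\]")
})
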