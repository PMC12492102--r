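test_that("Mann-Whitney exact path matches hand-enumerated examples", {
  r <- mann_whitney(c(5, 6, 7), c(1, 2, 3), alternative = "greater")
  expect_equal(r$statistic, 9)
  expect_equal(r$p_value, 0.05) # 1 of the 20 labelings reaches U >= 9
  expect_equal(r$method, "exact")

  r2 <- mann_whitney(c(1, 2), c(1, 2), alternative = "two_sided")
  expect_equal(r2$p_value, 1)

  r3 <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4), alternative = "greater")
  expect_equal(r3$statistic, 8) # midrank symmetry

  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("exact p equals the pair-counting permutation oracle on random small samples", {
  set.seed(11)
  for (i in 1:60) {
    na <- sample(1:5, 1); nb <- sample(1:5, 1)
    # integer values induce frequent ties
    a <- sample(0:4, na, replace = TRUE)
    b <- sample(0:4, nb, replace = TRUE)
    alt <- sample(c("greater", "less", "two_sided"), 1)
    expect_equal(mann_whitney(a, b, alt)$p_value, mw_oracle(a, b, alt),
                 tolerance = 1e-12,
                 info = sprintf("a=%s b=%s alt=%s", toString(a), toString(b), alt))
  }
})

test_that("exact p agrees with wilcox.test when there are no ties", {
  set.seed(12)
  for (i in 1:20) {
    a <- sample(1:100, 5); b <- setdiff(sample(1:100, 12), a)[1:5]
    p_pkg <- mann_whitney(a, b, "greater")$p_value
    p_ref <- stats::wilcox.test(a, b, alternative = "greater",
                                exact = TRUE)$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-10)
  }
})

test_that("one-sided test holds its nominal level under the null", {
  set.seed(13)
  n_rep <- 10000L
  rej <- 0L
  for (i in seq_len(n_rep)) {
    x <- stats::rnorm(20); y <- stats::rnorm(20)
    if (mann_whitney(x, y, "greater")$p_value < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / n_rep, 0.04)
  expect_lt(rej / n_rep, 0.06)
})

test_that("chi-square on 2x2 tables matches textbook Pearson arithmetic", {
  r <- chi2_2x2(matrix(c(10, 2, 90, 98), nrow = 2))
  expect_equal(r$chi2, 5.6738, tolerance = 1e-4)
  expect_equal(r$odds_ratio, 5.4444, tolerance = 1e-4)
  expect_false(r$degenerate)

  hom <- chi2_2x2(matrix(c(5, 5, 5, 5), nrow = 2))
  expect_equal(hom$chi2, 0)
  expect_equal(hom$p_value, 1)
  expect_equal(hom$odds_ratio, 1)

  hald <- chi2_2x2(matrix(c(5, 0, 35, 30), nrow = 2))
  expect_equal(hald$odds_ratio, (5.5 * 30.5) / (35.5 * 0.5), tolerance = 1e-8)
  expect_equal(hald$odds_ratio, 9.4507, tolerance = 1e-4)

  degen <- chi2_2x2(matrix(c(0, 0, 10, 20), nrow = 2))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)
})

test_that("chi-square is symmetric under row+column swap; OR inverts under row swap", {
  tab <- matrix(c(12, 3, 30, 45), nrow = 2)
  both <- tab[2:1, 2:1]
  expect_equal(chi2_2x2(tab)$chi2, chi2_2x2(both)$chi2)
  expect_equal(chi2_2x2(tab)$odds_ratio, chi2_2x2(both)$odds_ratio)
  rows <- tab[2:1, ]
  expect_equal(chi2_2x2(rows)$odds_ratio, 1 / chi2_2x2(tab)$odds_ratio)
  expect_equal(chi2_2x2(rows)$p_value, chi2_2x2(tab)$p_value)
})

test_that("BH adjustment reproduces the step-up computation and its guarantees", {
  expect_equal(bh_fdr(c(0.005, 0.01, 0.03, 0.04)), c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  expect_equal(bh_fdr(0.05), 0.05)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(14)
  for (i in 1:20) {
    p <- stats::runif(sample(2:50, 1))
    q <- bh_fdr(p)
    expect_true(all(q >= p))          # never decreases
    expect_true(all(q <= 1))          # capped
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12)) # monotone in sorted order
  }
})

test_that("coefficient of variation uses the sample standard deviation", {
  expect_equal(cov_value(c(5, 5, 5)), 0)
  expect_equal(cov_value(c(2, 4)), sqrt(2) / 3)
  expect_equal(cov_value(c(2, 4)), 0.4714, tolerance = 1e-4)
  expect_equal(cov_value(c(1, 2, 3)), 0.5)
  expect_true(is.na(cov_value(c(3))))
  expect_true(is.na(cov_value(c(-1, 1))))
})
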