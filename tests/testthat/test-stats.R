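test_that("Wilcoxon signed-rank reproduces the printed clinical p-values", {
  ## AQ T0 vs T1: all five differences positive, no rank ties
  res_aq <- wilcoxonSignedRank(aq_table[, "T0"], aq_table[, "T1"])
  expect_equal(round(res_aq$p.value, 3), 0.043)
  expect_equal(unname(res_aq$statistic), 15)
  expect_false(res_aq$tieCorrected)

  ## LQ T0 vs T1: two equal differences engage the tie correction
  res_lq <- wilcoxonSignedRank(lq_table[, "T0"], lq_table[, "T1"])
  expect_equal(round(res_lq$p.value, 3), 0.042)
  expect_true(res_lq$tieCorrected)

  ## T1 vs T2 not significant, matching the reported pattern
  expect_gt(wilcoxonSignedRank(aq_table[, "T1"], aq_table[, "T2"])$p.value, 0.05)
})

test_that("Wilcoxon handles equal differences via one tie group and is antisymmetric", {
  x <- c(10, 20, 30, 40, 50)
  res <- wilcoxonSignedRank(x, x + 3)
  expect_equal(unname(res$statistic), 15)          # W+ in {0, 15}
  expect_equal(res$zValue, 7.5 / sqrt(11.25))      # variance 13.75 - (5^3-5)/48
  res_rev <- wilcoxonSignedRank(x + 3, x)
  expect_equal(res_rev$zValue, -res$zValue)
  expect_equal(res_rev$p.value, res$p.value)
  expect_equal(unname(res_rev$statistic), 0)

  expect_error(wilcoxonSignedRank(x, x), "all differences are zero")
  expect_error(wilcoxonSignedRank(1:3, 1:4), "equal length")
})

test_that("Wilcoxon agrees with the base-R asymptotic tie-corrected reference", {
  set.seed(400)
  for (i in 1:20) {
    x <- round(rnorm(12), 1)
    y <- round(rnorm(12), 1)
    if (all(y - x == 0)) next
    ours <- wilcoxonSignedRank(x, y)$p.value
    ref <- suppressWarnings(
      wilcox.test(y, x, paired = TRUE, exact = FALSE, correct = FALSE))$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("Wilcoxon asymptotic null rejection rate is near nominal", {
  set.seed(401)
  rej <- mean(replicate(2000, {
    x <- rnorm(20); y <- rnorm(20)
    wilcoxonSignedRank(x, y)$p.value < 0.05
  }))
  ## binomial 99% CI half-width at p = .05, n = 2000 is ~0.0125
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.065)
})

test_that("Friedman reproduces the printed longitudinal p-values for AQ and LQ", {
  for (tab in list(aq_table, lq_table)) {
    res <- friedmanRankTest(tab)
    expect_equal(res$p.value, 0.0498, tolerance = 1e-3)
    ## the printed three-decimal value reflects truncation
    expect_equal(floor(res$p.value * 1000) / 1000, 0.049)
    expect_true(res$tieCorrected)  # one patient has tied scores
  }
})

test_that("Friedman closed form: identical monotone patterns give chi-squared 10", {
  m <- matrix(rep(c(1, 5, 9), each = 5), 5, 3)
  res <- friedmanRankTest(m)
  expect_equal(unname(res$statistic), 10)
  expect_equal(res$p.value, exp(-5))
})

test_that("Friedman is invariant to row permutation and per-subject shifts", {
  set.seed(402)
  m <- matrix(rnorm(15), 5, 3)
  base <- friedmanRankTest(m)$p.value
  expect_equal(friedmanRankTest(m[sample(5), ])$p.value, base)
  expect_equal(friedmanRankTest(m + rnorm(5))$p.value, base)
  ## Wilcoxon shares the shift invariance
  w0 <- wilcoxonSignedRank(m[, 1], m[, 2])$p.value
  expect_equal(wilcoxonSignedRank(m[, 1] + 7, m[, 2] + 7)$p.value, w0)
})

test_that("Friedman agrees with the base-R tie-corrected reference", {
  set.seed(403)
  for (i in 1:10) {
    m <- matrix(round(rnorm(18), 1), 6, 3)
    expect_equal(friedmanRankTest(m)$p.value, friedman.test(m)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("for two conditions Friedman orders exactly like the sign-pattern permutation null", {
  ## n = 4 subjects, all 16 sign patterns of a fixed nonzero difference:
  ## the Friedman statistic must be monotone in the two-sided exact
  ## sign-permutation p computed by brute-force enumeration
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 4)))
  stat <- perm_p <- numeric(nrow(signs))
  for (i in seq_len(nrow(signs))) {
    d <- signs[i, ]
    m <- cbind(0, d)
    stat[i] <- unname(friedmanRankTest(m)$statistic)
    k <- sum(d > 0)
    ## exact two-sided sign-test p via enumeration of all 16 patterns
    perm_p[i] <- mean(abs(colSums(t(signs))) >= abs(sum(d)))
  }
  expect_equal(cor(stat, -perm_p, method = "spearman"), 1)
})

test_that("normal upper tail matches the strong-connectivity calibration", {
  expect_equal(normalUpperTail(0), 0.5)
  expect_equal(round(100 * normalUpperTail(1), 2), 15.87)
  z <- c(-2, -0.5, 0.3, 1.7)
  expect_equal(normalUpperTail(z) + normalUpperTail(-z), rep(1, 4))
})
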