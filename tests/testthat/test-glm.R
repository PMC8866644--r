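test_that("canonical HRF peaks near 6 s, starts at zero, and is single-signed without undershoot", {
  for (fs in c(2, 10)) {
    k <- canonicalHrf(fs)
    expect_equal((which.max(k) - 1) / fs, 6, tolerance = 0.5 / 6)
    expect_equal(k[1], 0)
    expect_equal(max(k), 1)
  }
  k0 <- canonicalHrf(10, hrfParams(undershootRatio = 0))
  expect_true(all(k0 >= 0))
  expect_warning(canonicalHrf(10, hrfParams(kernelLength = 10)), "undershoot")
})

test_that("design matrix has the prescribed drift dimension and balanced task column", {
  d <- makeBlockDesign(120, 6, 30, fs = 2)
  kern <- canonicalHrf(2)
  X <- buildDesignMatrix(d, kern, dctCutoff = 128)
  expect_equal(sum(grepl("^dct", colnames(X))), 7)  # floor(2*480/128)
  expect_equal(colnames(X)[1], "task")
  expect_equal(colnames(X)[ncol(X)], "intercept")

  ## DCT columns mutually orthogonal
  D <- X[, grepl("^dct", colnames(X)), drop = FALSE]
  G <- unname(crossprod(D))
  expect_equal(G, diag(diag(G)), tolerance = 1e-8)

  ## infinite cutoff: no drift columns
  X0 <- buildDesignMatrix(d, kern, dctCutoff = Inf)
  expect_equal(colnames(X0), c("task", "intercept"))

  ## task column balances over the post-rest interval (small residual from
  ## kernel truncation at the recording end)
  post <- (seq_len(nrow(X)) - 1) / 2 >= 120 + 32  # past rest + kernel support
  expect_lt(abs(sum(X[post, "task"])) / sum(abs(X[post, "task"])), 0.1)

  ## a degenerate (all-zero) kernel empties the task column: rank deficiency
  expect_error(buildDesignMatrix(d, rep(0, 10), dctCutoff = 128),
               "rank deficient.*task")
})

test_that("with an identity kernel the t-statistic matches the correlation closed form", {
  d <- makeBlockDesign(120, 6, 30, fs = 2)
  kern <- canonicalHrf(2)
  X <- buildDesignMatrix(d, kern, dctCutoff = Inf)
  set.seed(101)
  y <- rnorm(nrow(X))
  fit <- precolorFit(y, X, kernel = 1)
  r <- cor(y, X[, "task"])
  df <- nrow(X) - 2
  expect_equal(fit$t, r * sqrt(df / (1 - r^2)), tolerance = 1e-10)
  expect_equal(attr(fit, "effDf"), df, tolerance = 1e-8)
})

test_that("a perfect task response is detected at any practical threshold", {
  d <- makeBlockDesign(120, 6, 30, fs = 2)
  kern <- canonicalHrf(2)
  X <- buildDesignMatrix(d, kern, dctCutoff = 128)
  fit <- precolorFit(X[, "task"], X, kern)
  expect_lt(fit$p, 1e-10)
  expect_gt(abs(fit$t), 50)
})

test_that("beta is scale-equivariant and t is scale- and drift-invariant", {
  d <- makeBlockDesign(120, 6, 30, fs = 2)
  kern <- canonicalHrf(2)
  X <- buildDesignMatrix(d, kern, dctCutoff = 128)
  op <- glmOperator(X, kern)
  set.seed(102)
  y <- 2e-7 * X[, "task"] + rnorm(nrow(X), sd = 1e-7)
  f1 <- precolorFit(y, X, op = op)
  f2 <- precolorFit(5 * y, X, op = op)
  expect_equal(f2$beta, 5 * f1$beta, tolerance = 1e-10)
  expect_equal(f2$t, f1$t, tolerance = 1e-10)

  ## adding any modelled drift component leaves the task t unchanged
  drift <- 3e-7 * X[, "dct2"] + 1e-6
  f3 <- precolorFit(y + drift, X, op = op)
  expect_equal(f3$t, f1$t, tolerance = 1e-8)
})

test_that("precolored inference is calibrated: type-I error near nominal under white noise", {
  d <- makeBlockDesign(120, 6, 30, fs = 2)
  kern <- canonicalHrf(2)
  X <- buildDesignMatrix(d, kern, dctCutoff = 128)
  op <- glmOperator(X, kern)
  set.seed(103)
  Y <- matrix(rnorm(nrow(X) * 200), ncol = 200)
  fit <- precolorFit(Y, X, op = op)
  rate <- mean(fit$p < 0.05)
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.09)
})

test_that("hotspot rule picks the largest |t| among passing channels and relaxes alpha as specified", {
  hs <- selectHotspot(c(1.0, 5.0, 2.0), c(0.4, 0.001, 0.1), 0.05, 0.001)
  expect_equal(hs$channel, 2L)
  expect_equal(hs$alphaUsed, 0.05)

  ## no channel below alpha0: alpha relaxes to the first grid value beyond 0.06
  hs2 <- selectHotspot(c(2, 3, 1), rep(0.06, 3), 0.05, 0.001)
  expect_equal(hs2$alphaUsed, 0.061)
  expect_equal(hs2$channel, 2L)

  ## |t| rule is sign-blind; ties break to the lowest channel id
  hs3 <- selectHotspot(c(-4, 4, 2), c(0.01, 0.01, 0.01), 0.05, 0.001)
  expect_equal(hs3$channel, 1L)
})

test_that("hotspot recovery frequency rises with SNR", {
  d <- makeBlockDesign(fs = 2)
  kern <- canonicalHrf(2)
  X <- buildDesignMatrix(d, kern, 128)
  op <- glmOperator(X, kern)
  rate <- sapply(c(1e-9, 5e-8), function(amp) {
    hits <- 0
    for (i in 1:25) {
      beta <- rep(0, 26); beta[10] <- amp
      sim <- simulateSubject(test_montage, d,
                             effectSpec(test_montage, betaTrue = beta),
                             seed = 500 + i)
      pre <- bandpassFilter(hemoglobinFromOD(odFromIntensity(sim$raw),
                                             test_optics, 3, 2))
      act <- activationMap(pre, d, op = op)
      hits <- hits + (act@hotspotChannel == 10)
    }
    hits / 25
  })
  expect_lt(rate[1], rate[2])
  expect_gte(rate[2], 0.9)
})
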