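test_that("latent covariance realizes the target block structure", {
  m <- test_montage
  ## one module over all channels with zero correlation -> identity
  spec <- quiet_spec(modules = list(all = 1:26), rWithin = 0, rBetween = 0)
  expect_equal(latentCovariance(spec, 26), diag(26))

  ## two 3-channel modules: exact targets, PSD
  spec2 <- quiet_spec(modules = list(a = 1:3, b = 4:6),
                      rWithin = 0.6, rBetween = 0.1)
  R <- latentCovariance(spec2, 6)
  expect_equal(diag(R), rep(1, 6))
  expect_equal(R[1, 2], 0.6)
  expect_equal(R[1, 4], 0.1)
  expect_true(min(eigen(R, symmetric = TRUE)$values) >= -1e-12)
  expect_error(latentCovariance(spec2, 4), "subsets")
})

test_that("simulated noise reproduces the latent correlations at large n", {
  spec <- effectSpec(test_montage, betaTrue = 0,
                     physio = data.frame(freq = numeric(), amplitude = numeric()),
                     driftSlope = 0, spikeRate = 0)
  R <- latentCovariance(spec, 26)
  d <- makeBlockDesign(0, 1, 10000, fs = 1, n_control = 0)
  sim <- simulateSubject(test_montage, d, spec, seed = 11)
  Rhat <- cor(oxyHb(sim$truth))
  expect_lt(max(abs(Rhat - R)), 0.05)
})

test_that("with all noise off the simulation is exactly beta times the regressor", {
  d <- makeBlockDesign(fs = 2)
  beta <- rep(0, 26); beta[7] <- 3e-8
  spec <- quiet_spec(betaTrue = beta)
  sim <- simulateSubject(test_montage, d, spec, seed = 5)
  expect_identical(oxyHb(sim$truth)[, 7], 3e-8 * sim$regressor)
  expect_true(all(oxyHb(sim$truth)[, -7] == 0))

  ## null signal: intensities constant at baseline
  sim0 <- simulateSubject(test_montage, d, quiet_spec(), seed = 5)
  expect_true(all(sim0$raw@data == 1))
})

test_that("the MBLL round trip recovers the noise-free ground truth", {
  d <- makeBlockDesign(fs = 2)
  beta <- rep(0, 26); beta[10] <- 5e-8
  sim <- simulateSubject(test_montage, d, quiet_spec(betaTrue = beta), seed = 6)
  hemo <- hemoglobinFromOD(odFromIntensity(sim$raw), test_optics,
                           separations = 3, fs = 2)
  scale <- max(abs(oxyHb(sim$truth)))
  expect_lt(max(abs(oxyHb(hemo) - oxyHb(sim$truth))) / scale, 1e-8)
  expect_lt(max(abs(deoxyHb(hemo) - deoxyHb(sim$truth))) / scale, 1e-8)
})

test_that("each physiological sinusoid averages to zero over whole periods", {
  d <- makeBlockDesign(0, 1, 480, fs = 5, n_control = 0)  # 480 s: whole periods at 1/0.25/0.1 Hz
  spec <- quiet_spec(physio = data.frame(freq = c(1, 0.25, 0.1),
                                         amplitude = c(1e-7, 8e-8, 5e-8)))
  sim <- simulateSubject(test_montage, d, spec, seed = 7)
  expect_lt(max(abs(colMeans(oxyHb(sim$truth)))), 1e-3 * 1e-7)
})

test_that("a single active channel has the maximum regressor correlation", {
  d <- makeBlockDesign(fs = 3.91)
  beta <- rep(0, 26); beta[10] <- 5e-8
  spec <- effectSpec(test_montage, betaTrue = beta)
  sim <- simulateSubject(test_montage, d, spec, seed = 8)
  cors <- abs(cor(oxyHb(sim$truth), sim$regressor))
  expect_equal(which.max(cors), 10L)
})

test_that("seeding contract: same seed identical, different seed different, no seed error", {
  d <- makeBlockDesign(fs = 2)
  spec <- effectSpec(test_montage)
  a <- simulateSubject(test_montage, d, spec, seed = 9)
  b <- simulateSubject(test_montage, d, spec, seed = 9)
  c <- simulateSubject(test_montage, d, spec, seed = 10)
  expect_identical(a$raw@data, b$raw@data)
  expect_false(identical(a$raw@data, c$raw@data))
  expect_error(simulateSubject(test_montage, d, spec), "seed is mandatory")
})

test_that("cohort simulation yields the full subject x session grid of recordings", {
  d <- makeBlockDesign(fs = 2)
  coh <- simulateCohort(5, c("T0", "T1", "T2"), test_montage, d, seed = 20)
  expect_equal(length(coh$recordings), 5)
  for (s in coh$subjects) {
    expect_named(coh$recordings[[s]], c("T0", "T1", "T2"))
    for (ses in coh$sessions) {
      dm <- dim(coh$recordings[[s]][[ses]]$raw@data)
      expect_equal(dm, c(floor(480 * 2), 26, 2))
    }
  }
  ## per-subject active channels follow the documented default sites
  expect_equal(coh$activeChannels, c(5, 8, 10, 10, 11))
  expect_error(
    simulateCohort(2, c("T0", "T1"), test_montage, d,
                   overrides = list(T9 = list(ar = 0)), seed = 1),
    "unknown session label")
})

test_that("session overrides change only the targeted session", {
  d <- makeBlockDesign(fs = 2)
  spec <- effectSpec(test_montage)
  rw <- spec@rWithin
  rw[grep("^left", names(rw))] <- 0.6
  coh <- simulateCohort(2, c("A", "B"), test_montage, d, spec,
                        overrides = list(B = list(rWithin = rw)), seed = 30)
  ## same master seed without override: session A identical, B differs
  coh0 <- simulateCohort(2, c("A", "B"), test_montage, d, spec, seed = 30)
  expect_identical(coh$recordings$S01$A$raw@data, coh0$recordings$S01$A$raw@data)
  expect_false(identical(coh$recordings$S01$B$raw@data,
                         coh0$recordings$S01$B$raw@data))
})
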