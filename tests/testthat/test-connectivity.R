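series_from_matrix <- function(x, fs = 1) {
  new("HemoTimeSeries", samplingRate = fs, oxy = x, deoxy = -0.3 * x)
}

test_that("correlation matrix is symmetric with masked diagonal and catches duplicates", {
  set.seed(200)
  x <- matrix(rnorm(300), 100, 3)
  x <- cbind(x, x[, 2])  # channel 4 duplicates channel 2
  cm <- correlationMatrix(series_from_matrix(x))
  expect_true(all(is.na(diag(cm@r))))
  expect_equal(cm@r[2, 4], 1)
  expect_equal(cm@r, t(cm@r))
  ## perfect correlation: z masked, not infinite
  expect_true(is.na(cm@z[2, 4]))
  ## finite entries obey z = atanh(r)
  ok <- which(is.finite(cm@z))
  expect_equal(cm@z[ok], atanh(cm@r[ok]))
})

test_that("independent channels decorrelate at large n and latent pairs are recovered", {
  set.seed(201)
  x <- matrix(rnorm(10000 * 5), ncol = 5)
  cm <- correlationMatrix(series_from_matrix(x))
  expect_lt(max(abs(cm@r[upper.tri(cm@r)])), 0.05)

  ## a pair with latent r = 0.6
  R <- diag(5); R[1, 2] <- R[2, 1] <- 0.6
  y <- x %*% chol(R)
  cm2 <- correlationMatrix(series_from_matrix(y))
  expect_equal(cm2@r[1, 2], 0.6, tolerance = 0.05)
})

test_that("zero-variance channels warn and yield undefined pairs; short windows are refused", {
  x <- cbind(rnorm(100), rep(1, 100))
  expect_warning(cm <- correlationMatrix(series_from_matrix(x)), "zero-variance")
  expect_true(is.na(cm@r[1, 2]))
  expect_error(correlationMatrix(series_from_matrix(matrix(rnorm(20), 10, 2))),
               "30 samples")
})

test_that("task-blocks window restricts the correlation to task samples", {
  d <- makeBlockDesign(10, 2, 10, fs = 2)
  n <- nSamples(d)
  task <- taskIndicator(d) == 1
  set.seed(202)
  x <- matrix(rnorm(2 * n), ncol = 2)
  x[task, 2] <- x[task, 1]  # identical inside task blocks only
  cm <- correlationMatrix(series_from_matrix(x, 2), "task_blocks", design = d)
  expect_equal(cm@r[1, 2], 1)
  cm_full <- correlationMatrix(series_from_matrix(x, 2))
  expect_lt(cm_full@r[1, 2], 1)
  expect_error(correlationMatrix(series_from_matrix(x, 2), "task_blocks"),
               "block design")
})

test_that("fisherZ matches atanh, is odd, strictly increasing, and guards |r| = 1", {
  expect_equal(fisherZ(0), 0)
  expect_equal(fisherZ(0.76159), 1, tolerance = 1e-4)
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(fisherZ(-r), -fisherZ(r))
  expect_true(all(diff(fisherZ(r)) > 0))
  expect_warning(z1 <- fisherZ(1), "infinite")
  expect_equal(z1, Inf)
  expect_error(fisherZ(1.2), "exceed")
})

test_that("group averaging is the pairwise-complete elementwise mean of z", {
  set.seed(203)
  zs <- replicate(5, {
    z <- matrix(rnorm(16), 4, 4)
    z <- (z + t(z)) / 2; diag(z) <- NA
    z
  }, simplify = FALSE)
  avg <- groupAverage(zs)
  brute <- Reduce(`+`, zs) / 5
  expect_equal(avg[upper.tri(avg)], brute[upper.tri(brute)])

  expect_equal(unname(groupAverage(zs[1])[2, 3]), zs[[1]][2, 3])
  opp <- groupAverage(list(zs[[1]], -zs[[1]]))
  expect_true(all(opp[upper.tri(opp)] == 0))

  ## entry undefined in one subject: mean over the rest; in all: NA
  za <- zs[[1]]; za[1, 2] <- za[2, 1] <- NA
  avg2 <- groupAverage(list(za, zs[[2]]))
  expect_equal(avg2[1, 2], zs[[2]][1, 2])
  expect_equal(attr(avg2, "n")[1, 2], 1L)
  zb <- zs[[2]]; zb[1, 2] <- zb[2, 1] <- NA
  expect_true(is.na(groupAverage(list(za, zb))[1, 2]))
})

test_that("strong-edge extraction thresholds, sorts, and is relabeling-invariant", {
  z <- matrix(0, 5, 5)
  expect_equal(nrow(strongEdges(z, 1.0)), 0)

  z[1, 3] <- z[3, 1] <- 1.4
  z[2, 5] <- z[5, 2] <- 2.1
  z[1, 2] <- z[2, 1] <- 0.9
  e <- strongEdges(z, 1.0)
  expect_equal(e$z, c(2.1, 1.4))
  expect_equal(e$ch_a, c(2, 1))
  expect_equal(e$ch_b, c(5, 3))
  expect_equal(as.character(e$thickness), c("thick", "medium"))

  ## threshold -Inf returns every unordered pair
  expect_equal(nrow(strongEdges(z, -Inf)), 10)

  ## permuting channels permutes pair names only
  perm <- c(3, 1, 5, 2, 4)
  zp <- z[perm, perm]
  ep <- strongEdges(zp, 1.0)
  orig_pairs <- mapply(function(a, b) paste(sort(c(perm[a], perm[b])), collapse = "-"),
                       ep$ch_a, ep$ch_b)
  expect_setequal(orig_pairs, c("2-5", "1-3"))
  expect_equal(sort(ep$z), sort(e$z))
})

test_that("a z = 1 cut on standard-normal weights retains the upper-tail fraction", {
  set.seed(204)
  n <- 400
  z <- matrix(0, n, n)
  z[upper.tri(z)] <- rnorm(n * (n - 1) / 2)
  z <- z + t(z)
  frac <- nrow(strongEdges(z, 1.0)) / (n * (n - 1) / 2)
  expect_equal(frac, normalUpperTail(1), tolerance = 0.02)
})
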