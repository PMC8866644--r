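test_that("sparsity thresholding takes exactly the top-weight pairs", {
  set.seed(300)
  w <- matrix(0, 4, 4)
  w[upper.tri(w)] <- c(6, 5, 4, 3, 2, 1) / 10
  w <- w + t(w)

  expect_equal(sum(thresholdBySparsity(w, 0)) / 2, 0)
  expect_equal(sum(thresholdBySparsity(w, 1)) / 2, 6)

  adj <- thresholdBySparsity(w, 0.5)
  expect_equal(sum(adj) / 2, 3)
  ## sort-and-take oracle: the three largest weights
  cut <- sort(w[upper.tri(w)], decreasing = TRUE)[3]
  expect_true(all(w[adj == 1] >= cut))
  expect_equal(attr(adj, "sparsity"), 0.5)

  ## nestedness: the edge set only grows with sparsity
  prev <- thresholdBySparsity(w, 0)
  for (S in seq(0.1, 1, by = 0.1)) {
    cur <- thresholdBySparsity(w, S)
    expect_true(all(cur[prev == 1] == 1))
    prev <- cur
  }

  ## undefined weights are excluded from the ranking
  w2 <- w; w2[1, 2] <- w2[2, 1] <- NA
  expect_warning(adj2 <- thresholdBySparsity(w2, 1), "undefined")
  expect_equal(adj2[1, 2], 1)  # complete graph still fills every pair at S = 1
  expect_warning(adj3 <- thresholdBySparsity(w2, 0.5), "undefined")
  expect_equal(adj3[1, 2], 0)  # but the NA pair ranks last before that
})

test_that("metric closed forms: triangle, path, complete graph", {
  tri <- matrix(1, 3, 3) - diag(3)
  expect_equal(clusteringCoefficient(tri), 1)
  expect_equal(globalEfficiency(tri), 1)

  path <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  expect_equal(clusteringCoefficient(path), 0)
  expect_equal(globalEfficiency(path), (1 + 1 + 0.5) / 3)

  k5 <- matrix(1, 5, 5) - diag(5)
  expect_equal(clusteringCoefficient(k5), 1)
  expect_equal(globalEfficiency(k5), 1)

  ## disconnected pairs contribute zero
  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 1
  expect_equal(globalEfficiency(iso), 2 / 6)
})

test_that("metrics agree exactly with brute-force oracles on random graphs", {
  set.seed(301)
  for (rep in 1:50) {
    n <- sample(2:8, 1)
    adj <- random_adjacency(n, runif(1, 0.2, 0.8))
    expect_equal(clusteringCoefficient(adj), brute_clustering(adj))
    expect_equal(globalEfficiency(adj), brute_efficiency(adj))
  }
})

test_that("metrics are invariant to node relabeling", {
  set.seed(302)
  adj <- random_adjacency(7, 0.5)
  perm <- sample(7)
  expect_equal(clusteringCoefficient(adj[perm, perm]), clusteringCoefficient(adj))
  expect_equal(globalEfficiency(adj[perm, perm]), globalEfficiency(adj))
})

test_that("sparsity profiles end at the complete graph and efficiency never decreases", {
  set.seed(303)
  w <- matrix(0, 8, 8)
  w[upper.tri(w)] <- rnorm(28)
  w <- w + t(w); diag(w) <- NA
  grid <- seq(0.1, 1, by = 0.1)
  prof <- sparsityProfile(w, 1:8, grid)
  expect_equal(prof$clustering[length(grid)], 1)
  expect_equal(prof$efficiency[length(grid)], 1)
  expect_true(all(diff(prof$efficiency) >= -1e-12))
  expect_true(all(prof$clustering >= 0 & prof$clustering <= 1))
  ## profile equals direct per-point recomputation
  for (i in c(3, 7)) {
    adj <- thresholdBySparsity(w, grid[i])
    expect_equal(prof$clustering[i], clusteringCoefficient(adj))
    expect_equal(prof$efficiency[i], globalEfficiency(adj))
  }
  expect_error(sparsityProfile(w, 1:2, grid), "3 nodes")
})

make_profile <- function(values, session, grid = seq(0.2, 1, by = 0.2)) {
  new("NetworkProfile", hemisphere = "left", session = session,
      sparsity = grid, clustering = values, efficiency = values,
      subjects = sprintf("S%02d", seq_len(nrow(values))))
}

test_that("profile comparison finds no ranges when sessions are identical and at alpha 0", {
  set.seed(304)
  v <- matrix(runif(25), 5, 5)
  a <- make_profile(v, "T0")
  b <- make_profile(v, "T1")
  cmp <- compareProfiles(a, b, "clustering", alpha = 0.1)
  expect_equal(nrow(cmp$ranges), 0)

  v2 <- v + matrix(runif(25, 0.01, 0.1), 5, 5)
  cmp0 <- compareProfiles(a, make_profile(v2, "T1"), "clustering", alpha = 0)
  expect_equal(nrow(cmp0$ranges), 0)
})

test_that("profile comparison reports contiguous significant ranges with direction", {
  set.seed(305)
  ## binary-exact values so the +0.25 shift gives exactly equal differences
  v <- matrix(sample.int(64, 25, replace = TRUE) / 128, 5, 5)
  v2 <- v
  v2[, 2:3] <- v[, 2:3] + 0.25  # all five subjects higher at grid points 2-3
  cmp <- compareProfiles(make_profile(v, "T0"), make_profile(v2, "T1"),
                         "clustering", alpha = 0.1)
  expect_equal(nrow(cmp$ranges), 1)
  expect_equal(cmp$ranges$start, 0.4)
  expect_equal(cmp$ranges$end, 0.6)
  expect_equal(cmp$ranges$direction, "B>A")
  expect_true(cmp$ranges$pMin <= cmp$ranges$pMax)
  ## the per-point p at an all-positive n = 5 difference (one tie group)
  expect_equal(cmp$points$p[2], 2 * pnorm(-7.5 / sqrt(11.25)))
})

test_that("profile comparison enforces matching grids and enough subjects", {
  v <- matrix(runif(15), 3, 5)
  a <- make_profile(v, "T0")
  expect_error(compareProfiles(a, a, "clustering"), "4 subjects")
  v5 <- matrix(runif(25), 5, 5)
  b <- make_profile(v5, "T1", grid = seq(0.1, 0.5, by = 0.1))
  expect_error(compareProfiles(make_profile(v5, "T0"), b, "clustering"),
               "sparsity grid")
})
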