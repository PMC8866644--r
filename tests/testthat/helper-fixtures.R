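options(nirsnet.quiet = TRUE)

## cached objects shared across tests (deterministic, cheap to build)
test_optics <- suppressMessages(opticsParams())
test_montage <- defaultMontage()

## Table 2 worked-example scores (verified against the packaged fixture)
aq_table <- cbind(T0 = c(52.0, 27.6, 97.6, 47.8, 63.6),
                  T1 = c(56.8, 34.4, 99.0, 56.4, 67.0),
                  T2 = c(55.6, 38.4, 99.0, 55.6, 59.0))
lq_table <- cbind(T0 = c(53.9, 25.0, 98.4, 40.1, 57.1),
                  T1 = c(58.4, 33.1, 99.5, 51.7, 61.6),
                  T2 = c(57.8, 35.4, 99.5, 50.1, 54.3))

## noise-free effect specification (all stochastic components off)
quiet_spec <- function(montage = test_montage,
                       physio = data.frame(freq = numeric(),
                                           amplitude = numeric()), ...) {
  effectSpec(montage, innovationSd = 0, physio = physio,
             driftSlope = 0, spikeRate = 0, deoxyNoiseSd = 0, ...)
}

## random binary symmetric adjacency without self-loops
random_adjacency <- function(n, p = 0.4) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}

## brute-force oracles, deliberately independent of the implementation:
## triangle enumeration over explicit node triples
brute_clustering <- function(adj) {
  n <- nrow(adj)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in seq_len(k - 1))
      for (b in (a + 1):k)
        if (adj[nb[a], nb[b]] == 1) tri <- tri + 1
    ci[i] <- 2 * tri / (k * (k - 1))
  }
  mean(ci)
}

## all-pairs shortest paths by Floyd-Warshall
brute_efficiency <- function(adj) {
  n <- nrow(adj)
  D <- ifelse(adj == 1, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

## preprocess one simulated recording the way the pipeline does
preprocess_sim <- function(sim, montage = test_montage, fs = 3.91) {
  hemo <- hemoglobinFromOD(odFromIntensity(sim$raw), test_optics,
                           separations = channelTable(montage)$separation,
                           fs = fs)
  bandpassFilter(hemo)
}
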