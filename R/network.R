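## Sparsity-thresholded binary undirected graphs and the two global metrics
## profiled against sparsity: clustering coefficient and global efficiency.

#' Binarize a weight matrix at a sparsity level
#'
#' Retains the \code{m = round(S * n(n-1)/2)} largest-weight unordered pairs
#' as edges of a binary undirected graph. Ranking is on the signed weight
#' (most positive first); ties at the cut resolve by lexicographic pair
#' order. Undefined weights are excluded from the ranking with a warning.
#'
#' @param weights symmetric numeric matrix (e.g. mean Fisher z).
#' @param S sparsity in [0, 1]: fraction of possible edges retained.
#' @param rankBy \code{"signed"} (default) or \code{"absolute"} edge
#'   ranking.
#' @return binary adjacency matrix (0/1, symmetric, zero diagonal) with
#'   attribute \code{"sparsity"}.
#' @export
thresholdBySparsity <- function(weights, S, rankBy = c("signed", "absolute")) {
  rankBy <- match.arg(rankBy)
  stopifnot(S >= 0, S <= 1, nrow(weights) == ncol(weights))
  n <- nrow(weights)
  ut <- which(upper.tri(weights), arr.ind = TRUE)
  w <- weights[ut]
  if (anyNA(w)) {
    warning(sum(is.na(w)), " undefined weight(s) excluded from ranking")
  }
  key <- if (rankBy == "absolute") abs(w) else w
  key[is.na(key)] <- -Inf
  m <- round(S * n * (n - 1) / 2)
  adj <- matrix(0, n, n)
  if (m > 0) {
    o <- order(-key, ut[, 1], ut[, 2])
    take <- o[seq_len(min(m, length(o)))]
    adj[ut[take, , drop = FALSE]] <- 1
    adj <- adj + t(adj)
  }
  attr(adj, "sparsity") <- S
  adj
}

#' Global clustering coefficient
#'
#' Mean over nodes of the local clustering coefficient
#' \code{C_i = 2 t_i / (k_i (k_i - 1))}, where \code{t_i} is the number of
#' triangles through node i and \code{k_i} its degree; \code{C_i = 0} for
#' degree < 2.
#'
#' @param adj binary symmetric adjacency matrix without self-loops.
#' @return C in [0, 1].
#' @examples
#' tri <- matrix(1, 3, 3) - diag(3)
#' clusteringCoefficient(tri)  # 1
#' @export
clusteringCoefficient <- function(adj) {
  n <- nrow(adj)
  if (n < 1) stop("need at least one node")
  k <- rowSums(adj)
  tri2 <- diag(adj %*% adj %*% adj)  # 2 * triangles per node
  ci <- ifelse(k >= 2, tri2 / (k * (k - 1)), 0)
  mean(ci)
}

bfs_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- adj > 0
  D[reach] <- 1
  frontier <- reach
  l <- 1
  while (any(frontier) && l < n) {
    nxt <- (frontier %*% adj) > 0
    new_idx <- nxt & !is.finite(D)
    if (!any(new_idx)) break
    D[new_idx] <- l + 1
    frontier <- new_idx
    l <- l + 1
  }
  D
}

#' Global efficiency
#'
#' \code{E = mean over ordered pairs of 1 / d_ij}, with \code{d_ij} the
#' shortest-path hop distance; disconnected pairs contribute 0.
#'
#' @param adj binary symmetric adjacency matrix without self-loops.
#' @return E in [0, 1].
#' @examples
#' path3 <- rbind(c(0,1,0), c(1,0,1), c(0,1,0))
#' globalEfficiency(path3)  # (1 + 1 + 0.5) / 3
#' @export
globalEfficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) stop("need at least two nodes")
  D <- bfs_distances(adj)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Metric-vs-sparsity profile of one subject's weights
#'
#' Restricts the weight matrix to the given node set (edge ranks are
#' recomputed within the subgraph, so sparsity is local to it) and computes
#' clustering coefficient and global efficiency at every grid point.
#'
#' @param weights symmetric weight matrix over all channels.
#' @param nodes integer channel ids of the subgraph (>= 3).
#' @param grid sparsity grid within [0, 1].
#' @param rankBy edge ranking passed to [thresholdBySparsity()].
#' @return data.frame(sparsity, clustering, efficiency).
#' @export
sparsityProfile <- function(weights, nodes, grid = seq(0.01, 1, by = 0.01),
                            rankBy = "signed") {
  if (length(nodes) < 3) stop("subgraph needs at least 3 nodes")
  if (any(grid < 0 | grid > 1)) stop("sparsity grid must lie in [0, 1]")
  w <- weights[nodes, nodes, drop = FALSE]
  C <- E <- numeric(length(grid))
  for (i in seq_along(grid)) {
    adj <- thresholdBySparsity(w, grid[i], rankBy = rankBy)
    C[i] <- clusteringCoefficient(adj)
    E[i] <- globalEfficiency(adj)
  }
  data.frame(sparsity = grid, clustering = C, efficiency = E)
}

#' Per-session hemispheric network profiles of a cohort's matrices
#'
#' Builds a \linkS4class{NetworkProfile} (per-subject metric-vs-sparsity
#' curves) for one hemisphere and session from the subjects' connectivity
#' matrices.
#'
#' @param matrices named list (by subject) of \linkS4class{ConnectivityMatrix}
#'   for one session.
#' @param montage A \linkS4class{Montage}.
#' @param hemisphere \code{"left"}, \code{"right"} or \code{"whole"}.
#' @param session session label.
#' @param grid sparsity grid.
#' @param rankBy edge ranking.
#' @return A \linkS4class{NetworkProfile}.
#' @export
networkProfile <- function(matrices, montage, hemisphere, session,
                           grid = seq(0.01, 1, by = 0.01), rankBy = "signed") {
  nodes <- if (hemisphere == "whole") seq_len(nChannels(montage))
           else hemisphereChannels(montage, hemisphere)
  C <- E <- matrix(NA_real_, length(matrices), length(grid))
  for (s in seq_along(matrices)) {
    prof <- sparsityProfile(matrices[[s]]@z, nodes, grid, rankBy)
    C[s, ] <- prof$clustering
    E[s, ] <- prof$efficiency
  }
  subj <- names(matrices) %||% sprintf("S%02d", seq_along(matrices))
  new("NetworkProfile", hemisphere = hemisphere, session = session,
      sparsity = grid, clustering = C, efficiency = E, subjects = subj)
}

#' Compare network profiles between two sessions
#'
#' At every sparsity grid point, a paired two-sided Wilcoxon signed-rank
#' test across subjects compares metric values of session B against session
#' A; contiguous runs of points with \code{p < alpha} are reported as
#' significant sparsity ranges with the min/max p over the run and the
#' direction of the median difference (B - A).
#'
#' Per-point alpha defaults to 0.1 with no multiplicity correction across
#' sparsity, the convention under which per-point p ranges are reported;
#' interpret ranges accordingly.
#'
#' @param A,B \linkS4class{NetworkProfile}s with identical subjects and
#'   grid.
#' @param metric \code{"clustering"} or \code{"efficiency"}.
#' @param alpha per-point significance level (default 0.1).
#' @return list with \code{points} (data.frame sparsity, p, medianDiff) and
#'   \code{ranges} (data.frame start, end, pMin, pMax, direction).
#' @export
compareProfiles <- function(A, B, metric = c("clustering", "efficiency"),
                            alpha = 0.1) {
  metric <- match.arg(metric)
  stopifnot(is(A, "NetworkProfile"), is(B, "NetworkProfile"))
  if (!identical(A@sparsity, B@sparsity))
    stop("profiles must share the sparsity grid")
  if (!identical(A@subjects, B@subjects))
    stop("profiles must cover the same subjects")
  if (nrow(A@clustering) < 4)
    stop("need at least 4 subjects for a nonzero-resolution paired test")
  ma <- slot(A, metric)
  mb <- slot(B, metric)
  g <- A@sparsity
  p <- med <- rep(NA_real_, length(g))
  for (i in seq_along(g)) {
    d <- mb[, i] - ma[, i]
    med[i] <- median(d)
    if (all(d == 0)) next  # undefined test; not significant
    p[i] <- wilcoxonSignedRank(ma[, i], mb[, i])$p.value
  }
  sig <- !is.na(p) & p < alpha
  ranges <- NULL
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (j in which(r$values)) {
    idx <- starts[j]:ends[j]
    ranges <- rbind(ranges, data.frame(
      start = g[starts[j]], end = g[ends[j]],
      pMin = min(p[idx]), pMax = max(p[idx]),
      direction = if (median(med[idx]) > 0) "B>A" else "B<A"))
  }
  if (is.null(ranges))
    ranges <- data.frame(start = numeric(), end = numeric(),
                         pMin = numeric(), pMax = numeric(),
                         direction = character())
  list(points = data.frame(sparsity = g, p = p, medianDiff = med),
       ranges = ranges)
}
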