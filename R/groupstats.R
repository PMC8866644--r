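## Nonparametric tests in the asymptotic, tie-corrected, no-continuity-
## correction convention: zero differences are dropped before ranking, tied
## ranks enter the variance correction, and p-values come from the normal /
## chi-squared approximations. These are the conventions under which the
## small-cohort clinical p-values of such studies are printed.

#' Paired Wilcoxon signed-rank test (asymptotic, tie-corrected)
#'
#' Ranks |y - x| after dropping zero differences, sums the positive ranks
#' W+, and refers
#' \deqn{z = (W^+ - n(n+1)/4) / \sqrt{n(n+1)(2n+1)/24 - \sum(t^3 - t)/48}}
#' (t the tied-rank group sizes) to the standard normal, two-sided, with no
#' continuity correction.
#'
#' @param x,y paired samples of equal length.
#' @return An object of class \code{"htest"} with the rank sum statistic,
#'   the normal approximation z, the two-sided p, the effective n and a
#'   tie-correction flag.
#' @examples
#' t0 <- c(52.0, 27.6, 97.6, 47.8, 63.6)
#' t1 <- c(56.8, 34.4, 99.0, 56.4, 67.0)
#' wilcoxonSignedRank(t0, t1)$p.value  # 0.043
#' @export
wilcoxonSignedRank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- y - x
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero: test undefined")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / 48
  v <- n * (n + 1) * (2 * n + 1) / 24 - tie_corr
  if (v <= 0) stop("degenerate variance (all ranks tied to zero)")
  z <- (w_pos - n * (n + 1) / 4) / sqrt(v)
  p <- 2 * pnorm(-abs(z))
  structure(list(
    statistic = c(`W+` = w_pos), parameter = c(n = n),
    zValue = z, p.value = p, tieCorrected = tie_corr > 0,
    method = "Wilcoxon signed-rank test (asymptotic, tie-corrected, no continuity correction)",
    data.name = paste(deparse1(substitute(x)), "vs", deparse1(substitute(y)))),
    class = "htest")
}

#' Friedman rank test (asymptotic, tie-corrected)
#'
#' Within-subject midranks across conditions; the tie-corrected statistic
#' \deqn{\chi^2 = (k-1) \sum_j (R_j - n(k+1)/2)^2 /
#'       (\sum_{ij} r_{ij}^2 - n k (k+1)^2 / 4)}
#' is referred to chi-squared with k - 1 degrees of freedom. Without ties
#' this reduces to the classical Friedman statistic.
#'
#' @param scores numeric matrix, subjects in rows, conditions in columns.
#' @return An object of class \code{"htest"}.
#' @examples
#' aq <- cbind(T0 = c(52.0, 27.6, 97.6, 47.8, 63.6),
#'             T1 = c(56.8, 34.4, 99.0, 56.4, 67.0),
#'             T2 = c(55.6, 38.4, 99.0, 55.6, 59.0))
#' friedmanRankTest(aq)$p.value  # 0.0498 (prints as 0.049)
#' @export
friedmanRankTest <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores); k <- ncol(scores)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 conditions")
  r <- t(apply(scores, 1, rank))
  Rj <- colSums(r)
  num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
  den <- sum(r^2) - n * k * (k + 1)^2 / 4
  if (den == 0) stop("degenerate denominator: all scores tied within every subject")
  stat <- num / den
  p <- pchisq(stat, df = k - 1, lower.tail = FALSE)
  structure(list(
    statistic = c(`Friedman chi-squared` = stat),
    parameter = c(df = k - 1, n = n),
    p.value = p, tieCorrected = any(apply(scores, 1, anyDuplicated) > 0),
    method = "Friedman rank test (asymptotic, tie-corrected)",
    data.name = deparse1(substitute(scores))),
    class = "htest")
}

#' Standard-normal upper-tail probability
#'
#' \code{1 - Phi(z)}; at the strong-connectivity threshold z = 1.0 this is
#' 0.1587 (15.87%), the fraction of standard-normal edge weights a z > 1
#' cut retains.
#'
#' @param z numeric value(s).
#' @return Upper-tail probability.
#' @examples
#' normalUpperTail(1.0)  # 0.1587
#' @export
normalUpperTail <- function(z) pnorm(z, lower.tail = FALSE)
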