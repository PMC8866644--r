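## Pairwise channel functional connectivity: Pearson correlation per
## unordered channel pair, Fisher z-transform for averaging and
## thresholding, group averaging on z, and strong-edge extraction.

#' Channel-pair Pearson correlation matrix
#'
#' Pearson correlation between every unordered pair of channels of the
#' processed oxyHb series, over the full recording or over the concatenated
#' task blocks. The diagonal is masked (NA); zero-variance channels yield NA
#' pairs with a warning. The Fisher z-transform of the matrix is stored
#' alongside (perfect correlations give infinite z and are masked).
#'
#' @param series A preprocessed \linkS4class{HemoTimeSeries}.
#' @param window \code{"full"} (default) or \code{"task_blocks"}.
#' @param design A \linkS4class{BlockDesign}; required for
#'   \code{window = "task_blocks"}.
#' @param subject,session identifiers carried into the result.
#' @return A \linkS4class{ConnectivityMatrix}.
#' @export
correlationMatrix <- function(series, window = c("full", "task_blocks"),
                              design = NULL, subject = "S01", session = "T0") {
  window <- match.arg(window)
  x <- oxyHb(series)
  if (window == "task_blocks") {
    if (is.null(design)) stop("task_blocks window requires the block design")
    idx <- which(taskIndicator(design)[seq_len(nrow(x))] == 1)
    x <- x[idx, , drop = FALSE]
  }
  if (nrow(x) < 30) stop("need at least 30 samples in the selected window")
  v <- apply(x, 2, var)
  if (any(v == 0))
    warning("zero-variance channel(s): ",
            paste(which(v == 0), collapse = ", "), "; their pairs are NA")
  r <- suppressWarnings(cor(x))
  r[!is.finite(r)] <- NA
  diag(r) <- NA
  z <- r
  at <- abs(r) < 1
  z[which(at)] <- atanh(r[which(at)])
  z[which(!at)] <- NA  # |r| = 1: infinite z, masked
  new("ConnectivityMatrix", r = r, z = z, subject = subject,
      session = session, window = window)
}

#' Fisher z-transform
#'
#' \code{z = atanh(r)}, the variance-stabilizing transform of a Pearson
#' correlation. Strictly increasing and odd. |r| = 1 maps to signed
#' infinity with a warning (mask before averaging).
#'
#' @param r correlation value(s) in [-1, 1].
#' @return Fisher z value(s).
#' @examples
#' fisherZ(0.76159)  # ~1.0
#' @export
fisherZ <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| must not exceed 1")
  if (any(abs(r) == 1, na.rm = TRUE))
    warning("|r| = 1 yields infinite z; mask before averaging")
  atanh(r)
}

#' Group-average Fisher-z matrix
#'
#' Elementwise mean of the z matrices across subjects, excluding undefined
#' entries pairwise; an entry undefined in every subject stays NA. The
#' number of contributing subjects per entry is attached as attribute
#' \code{"n"}.
#'
#' @param matrices list of \linkS4class{ConnectivityMatrix} (or plain z
#'   matrices) of identical dimension.
#' @return Mean-z matrix with attribute \code{"n"}.
#' @export
groupAverage <- function(matrices) {
  if (length(matrices) < 1) stop("need at least one matrix")
  zs <- lapply(matrices, function(m) if (is(m, "ConnectivityMatrix")) m@z else m)
  d <- dim(zs[[1]])
  if (!all(vapply(zs, function(z) identical(dim(z), d), logical(1))))
    stop("all matrices must share dimensions")
  sum_z <- matrix(0, d[1], d[2])
  n_ok <- matrix(0L, d[1], d[2])
  for (z in zs) {
    ok <- is.finite(z)
    sum_z[ok] <- sum_z[ok] + z[ok]
    n_ok <- n_ok + ok
  }
  out <- sum_z / n_ok
  out[n_ok == 0] <- NA
  attr(out, "n") <- n_ok
  out
}

#' Strong-connectivity edges
#'
#' Unordered channel pairs whose mean Fisher z exceeds the threshold
#' (default 1.0, the conventional strong-connectivity cut corresponding to
#' the upper 15.87% of a standard normal), sorted by descending z. A
#' line-thickness class for connectivity diagrams is included
#' (\code{thin}/\code{medium}/\code{thick} at z - threshold of 0.25 and
#' 0.5).
#'
#' @param meanZ symmetric mean-z matrix (e.g. from [groupAverage()]).
#' @param threshold z threshold (default 1.0).
#' @return data.frame(ch_a, ch_b, z, n_subjects, thickness).
#' @export
strongEdges <- function(meanZ, threshold = 1.0) {
  stopifnot(is.finite(threshold) || threshold == -Inf)
  n_mat <- attr(meanZ, "n")
  ut <- which(upper.tri(meanZ), arr.ind = TRUE)
  z <- meanZ[ut]
  keep <- which(!is.na(z) & z > threshold)
  ns <- if (!is.null(n_mat)) n_mat[ut[keep, , drop = FALSE]]
        else rep(NA_integer_, length(keep))
  out <- data.frame(ch_a = ut[keep, 1], ch_b = ut[keep, 2], z = z[keep],
                    n_subjects = ns)
  out <- out[order(-out$z, out$ch_a, out$ch_b), , drop = FALSE]
  rownames(out) <- NULL
  excess <- out$z - threshold
  out$thickness <- cut(excess, breaks = c(-Inf, 0.25, 0.5, Inf),
                       labels = c("thin", "medium", "thick"))
  out
}
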