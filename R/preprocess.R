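## Artifact handling and band-pass filtering of hemoglobin series. The
## band-pass is realized as a cascade of 4th-order Butterworth high-pass and
## low-pass sections, each applied forward-backward (zero-phase).

robust_sd <- function(x) {
  s <- mad(x, constant = 1.4826)
  if (s == 0) s <- sd(x)
  s
}

moving_median <- function(x, w) {
  w <- max(3L, as.integer(w))
  if (w %% 2 == 0) w <- w + 1L
  n <- length(x)
  half <- (w - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- median(x[lo:hi])
  }
  out
}

runs_to_segments <- function(flag, fs, channel, reason) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  if (!length(keep)) return(NULL)
  data.frame(channel = channel,
             start_s = (starts[keep] - 1) / fs,
             end_s = (ends[keep] - 1) / fs,
             reason = reason)
}

#' Detect spike and discontinuity artifacts
#'
#' Automated stand-in for manual artifact screening: a sample is flagged as
#' a spike when its deviation from a moving median exceeds \code{spike_z}
#' robust SDs, and as a discontinuity when the first difference exceeds
#' \code{jump_z} robust SDs of the differenced series. Flagged samples are
#' dilated by one neighbor on each side.
#'
#' @param series A \linkS4class{HemoTimeSeries} (oxyHb is screened).
#' @param spike_z,jump_z thresholds in robust-SD units (defaults 5).
#' @param window_s moving-median window in seconds (default 2); must span at
#'   least 3 samples.
#' @return An \linkS4class{ArtifactMask}.
#' @export
detectArtifacts <- function(series, spike_z = 5, jump_z = 5, window_s = 2) {
  x <- oxyHb(series)
  fs <- samplingRate(series)
  w <- window_s * fs
  if (w < 3) stop("window_s must span at least 3 samples")
  n <- nrow(x)
  half <- max(1L, as.integer(w) %/% 2L)
  flags <- matrix(FALSE, n, ncol(x))
  segs <- list()
  dilate <- function(f) f | c(f[-1], FALSE) | c(FALSE, f[-n])
  for (c in seq_len(ncol(x))) {
    xc <- x[, c]
    if (sd(xc) == 0) {
      warning("channel ", c, " is constant; no artifact flags")
      next
    }
    ## spike: deviation from the moving median; the uncentered boundary
    ## windows are excluded (covered by the jump detector instead)
    mm <- moving_median(xc, w)
    dev <- xc - mm
    interior <- (half + 1):(n - half)
    spike <- abs(dev) / robust_sd(dev[interior]) > spike_z
    spike[-interior] <- FALSE
    ## discontinuity: a large first difference that leaves the level
    ## shifted; large differences that revert at once are spikes
    d <- diff(xc)
    rs_d <- robust_sd(d)
    jump <- logical(n)
    k <- max(3L, half)
    for (i in which(abs(d) / rs_d > jump_z)) {
      pre <- median(xc[max(1, i - k + 1):i])
      post <- median(xc[(i + 1):min(n, i + k)])
      if (abs(post - pre) > 0.5 * jump_z * rs_d) jump[i:(i + 1)] <- TRUE
    }
    ## the moving-median residual stays offset near a level shift: suppress
    ## spike flags within half a window of any discontinuity
    jump_region <- jump
    for (j in seq_len(half)) jump_region <- dilate(jump_region)
    spike <- spike & !jump_region
    spike_d <- dilate(spike)
    jump_d <- dilate(jump)
    flags[, c] <- spike_d | jump_d
    segs[[length(segs) + 1]] <- runs_to_segments(spike_d & !jump_d, fs, c, "spike")
    segs[[length(segs) + 1]] <- runs_to_segments(jump_d, fs, c, "discontinuity")
  }
  segs <- do.call(rbind, segs)
  if (is.null(segs))
    segs <- data.frame(channel = integer(), start_s = numeric(),
                       end_s = numeric(), reason = character())
  segs <- segs[order(segs$channel, segs$start_s), , drop = FALSE]
  rownames(segs) <- NULL
  new("ArtifactMask", flags = flags, segments = segs)
}

#' Repair flagged samples
#'
#' Replaces flagged spans by linear interpolation between the nearest clean
#' neighbors (boundary spans are filled from the first/last clean value), or
#' by NA markers. Unflagged samples are returned bit-identical.
#'
#' @param series A \linkS4class{HemoTimeSeries}.
#' @param mask An \linkS4class{ArtifactMask} for the series.
#' @param method \code{"interpolate"} (default) or \code{"nan"}.
#' @return A repaired \linkS4class{HemoTimeSeries}.
#' @export
repairArtifacts <- function(series, mask, method = c("interpolate", "nan")) {
  method <- match.arg(method)
  flags <- mask@flags
  if (!identical(dim(flags), dim(oxyHb(series))))
    stop("mask dimensions do not match the series")
  fix <- function(m) {
    for (c in seq_len(ncol(m))) {
      f <- flags[, c]
      if (!any(f)) next
      if (all(f)) stop("channel ", c, " is fully flagged; cannot repair")
      if (method == "nan") { m[f, c] <- NA_real_; next }
      idx <- which(!f)
      m[f, c] <- approx(idx, m[idx, c], xout = which(f), rule = 2)$y
    }
    m
  }
  new("HemoTimeSeries", samplingRate = samplingRate(series),
      oxy = fix(oxyHb(series)), deoxy = fix(deoxyHb(series)))
}

#' Zero-phase band-pass filter
#'
#' Cascade of a 4th-order Butterworth high-pass at \code{low_Hz} and a
#' 4th-order Butterworth low-pass at \code{high_Hz}, each run
#' forward-backward (zero net phase). Defaults 0.01 and 0.2 Hz remove drift
#' and instrumental/physiological noise while preserving block-design task
#' frequencies. DC is rejected by the high-pass.
#'
#' @param series A \linkS4class{HemoTimeSeries}.
#' @param low_Hz high-pass cut-off (Hz).
#' @param high_Hz low-pass cut-off (Hz).
#' @param order Butterworth order per section (default 4).
#' @return The filtered \linkS4class{HemoTimeSeries}.
#' @export
bandpassFilter <- function(series, low_Hz = 0.01, high_Hz = 0.2, order = 4) {
  fs <- samplingRate(series)
  if (!(0 < low_Hz && low_Hz < high_Hz && high_Hz < fs / 2))
    stop("need 0 < low_Hz < high_Hz < Nyquist")
  n <- nrow(oxyHb(series))
  if (n / fs < 3 / low_Hz)
    stop("recording shorter than 3 filter time constants at ", low_Hz,
         " Hz; too short to filter")
  hp <- signal::butter(order, low_Hz / (fs / 2), type = "high")
  lp <- signal::butter(order, high_Hz / (fs / 2), type = "low")
  run <- function(m) {
    apply(m, 2, function(x) {
      x <- x - mean(x)
      x <- signal::filtfilt(hp, x)
      signal::filtfilt(lp, x)
    })
  }
  new("HemoTimeSeries", samplingRate = fs,
      oxy = run(oxyHb(series)), deoxy = run(deoxyHb(series)))
}

#' Export an artifact mask as an interval table
#'
#' Writes the flagged segments as a BED-like TSV (channel, start_s, end_s,
#' reason).
#'
#' @param mask An \linkS4class{ArtifactMask}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeArtifactMask <- function(mask, path) {
  utils::write.table(mask@segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
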