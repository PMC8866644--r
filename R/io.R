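## On-disk formats. Recordings travel as a documented wide CSV: commented
## metadata header, then a `time` column (seconds) and one column per
## channel x wavelength named chNN_<wavelength>. Montages are TSV
## (montage.R); configs are YAML (pipeline.R).

intensity_col_names <- function(n_ch, wavelengths) {
  as.vector(t(outer(seq_len(n_ch), wavelengths,
                    function(c, w) sprintf("ch%02d_%d", c, w))))
}

#' Write a recording as wide CSV
#'
#' Column layout: \code{time} in seconds, then \code{chNN_760},
#' \code{chNN_850} per channel. Sampling rate, wavelengths and per-column
#' baseline intensities are stored in commented header lines, so a read
#' after a write reproduces the object exactly (values are written with 17
#' significant digits).
#'
#' @param raw A \linkS4class{RawIntensity}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeIntensityCSV <- function(raw, path) {
  stopifnot(is(raw, "RawIntensity"))
  d <- dim(raw@data)
  cols <- intensity_col_names(d[2], raw@wavelengths)
  flat <- matrix(0, d[1], length(cols))
  for (c in seq_len(d[2]))
    for (l in seq_len(d[3]))
      flat[, (c - 1) * d[3] + l] <- raw@data[, c, l]
  base_flat <- as.vector(t(raw@baseline))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# nirsnet intensity CSV v1",
    sprintf("# sampling_rate_hz: %.17g", raw@samplingRate),
    sprintf("# wavelengths_nm: %s", paste(raw@wavelengths, collapse = ",")),
    sprintf("# baseline: %s", paste(sprintf("%.17g", base_flat), collapse = ","))),
    con)
  tvec <- (seq_len(d[1]) - 1) / raw@samplingRate
  writeLines(paste(c("time", cols), collapse = ","), con)
  body <- cbind(sprintf("%.17g", tvec),
                matrix(sprintf("%.17g", flat), nrow = d[1]))
  writeLines(apply(body, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Read a recording
#'
#' Reads a two-wavelength recording from the wide-CSV dialect written by
#' [writeIntensityCSV()]. When a montage is supplied, the file's channel
#' set must match it exactly (channel/montage mismatch is a distinct
#' error), both wavelengths must be present for every channel, and the time
#' column must be uniformly sampled.
#'
#' @param path file path.
#' @param format \code{"csv"} (the supported on-disk dialect).
#' @param montage optional \linkS4class{Montage} to validate against.
#' @return A \linkS4class{RawIntensity}.
#' @export
readTimeSeries <- function(path, format = c("csv"), montage = NULL) {
  format <- match.arg(format)
  readIntensityCSV(path, montage)
}

#' @rdname readTimeSeries
#' @export
readIntensityCSV <- function(path, montage = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 10)
  meta <- hdr[startsWith(hdr, "#")]
  get_meta <- function(key) {
    line <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    if (!length(line)) stop("missing metadata line '", key, "' in ", path)
    trimws(sub(paste0("^# ", key, ":"), "", line[1]))
  }
  fs <- as.numeric(get_meta("sampling_rate_hz"))
  wavelengths <- as.numeric(strsplit(get_meta("wavelengths_nm"), ",")[[1]])
  base_flat <- as.numeric(strsplit(get_meta("baseline"), ",")[[1]])
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!"time" %in% names(tab)) stop("CSV lacks a 'time' column")
  dt <- diff(tab$time)
  if (length(dt) && (max(dt) - min(dt)) > 1e-6 / fs)
    stop("non-uniform sampling in time column")
  chan_cols <- setdiff(names(tab), "time")
  parsed <- regmatches(chan_cols, regexec("^ch([0-9]+)_([0-9]+)$", chan_cols))
  if (any(lengths(parsed) != 3))
    stop("unrecognized channel column name(s): ",
         paste(chan_cols[lengths(parsed) != 3], collapse = ", "))
  ch_id <- as.integer(vapply(parsed, `[`, "", 2))
  wl <- as.numeric(vapply(parsed, `[`, "", 3))
  n_ch <- max(ch_id)
  if (length(setdiff(wavelengths, unique(wl))))
    stop("missing wavelength: file does not carry all declared wavelengths")
  for (c in unique(ch_id))
    if (!all(wavelengths %in% wl[ch_id == c]))
      stop("missing wavelength for channel ", c)
  if (!is.null(montage)) {
    want <- channelTable(montage)$channel
    if (!setequal(ch_id, want))
      stop("channel/montage mismatch: file channels {",
           paste(sort(unique(ch_id)), collapse = ","), "} vs montage {",
           paste(want, collapse = ","), "}")
    n_ch <- nChannels(montage)
  }
  n_wl <- length(wavelengths)
  dat <- array(NA_real_, dim = c(nrow(tab), n_ch, n_wl))
  for (j in seq_along(chan_cols)) {
    l <- match(wl[j], wavelengths)
    dat[, ch_id[j], l] <- tab[[chan_cols[j]]]
  }
  if (anyNA(dat)) stop("channel/montage mismatch: missing channel column(s)")
  baseline <- matrix(base_flat, n_ch, n_wl, byrow = TRUE)
  new("RawIntensity", samplingRate = fs, wavelengths = wavelengths,
      data = dat, baseline = baseline)
}

#' Write a simulated cohort to disk
#'
#' One wide-CSV recording per subject-session, the montage as TSV, and a
#' ground-truth sidecar JSON (per-recording seeds and true activation
#' amplitudes) so simulations are fully reconstructible.
#'
#' @param cohort a \code{"nirsCohort"} from [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMontage(cohort$montage, file.path(dir, "montage.tsv"))
  truth <- list(masterSeed = cohort$seed, recordings = list())
  for (s in cohort$subjects) {
    for (ses in cohort$sessions) {
      rec <- cohort$recordings[[s]][[ses]]
      fn <- sprintf("%s_%s.csv", s, ses)
      writeIntensityCSV(rec$raw, file.path(dir, fn))
      truth$recordings[[fn]] <- list(seed = rec$seed, betaTrue = rec$betaTrue)
    }
  }
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Packaged clinical scores (worked-example fixture)
#'
#' K-WAB scores of the five-patient motivating cohort: aphasia quotient
#' (AQ) and language quotient (LQ) at the three evaluation timepoints (T0
#' before treatment, T1 one day after, T2 one month after), plus the
#' baseline subsection scores. The fixture integrity is verified against a
#' stored checksum of the AQ/LQ columns.
#'
#' @return data.frame with one row per patient x session.
#' @examples
#' sc <- loadClinicalScores()
#' subset(sc, patient == 1 & session == "T0")$AQ  # 52.0
#' @export
loadClinicalScores <- function() {
  path <- system.file("extdata", "kwab_scores.tsv", package = "nirsnet")
  sc <- utils::read.delim(path)
  if (abs(sum(sc$AQ) + sum(sc$LQ) - 1785.7) > 1e-9)
    stop("clinical fixture corrupted: AQ/LQ checksum mismatch")
  if (any(sc$AQ < 0 | sc$AQ > 100) || any(sc$LQ < 0 | sc$LQ > 100))
    stop("clinical fixture corrupted: scores outside [0, 100]")
  if (anyDuplicated(sc[, c("patient", "session")]))
    stop("clinical fixture corrupted: duplicate patient x session record")
  sc
}

#' Packaged participant characteristics (worked-example fixture)
#'
#' Demographics, lesion characteristics, naming-test scores and the
#' per-patient stimulation site with its fNIRS channel id.
#'
#' @return data.frame, one row per patient.
#' @export
loadParticipants <- function() {
  path <- system.file("extdata", "participants.tsv", package = "nirsnet")
  utils::read.delim(path)
}

#' Score matrix for one measure across sessions
#'
#' Reshapes [loadClinicalScores()] output into a subjects x sessions matrix
#' for [friedmanRankTest()] / [wilcoxonSignedRank()].
#'
#' @param scores data.frame from [loadClinicalScores()].
#' @param measure \code{"AQ"} or \code{"LQ"}.
#' @param sessions session order.
#' @return numeric matrix, patients x sessions.
#' @export
scoreMatrix <- function(scores, measure = c("AQ", "LQ"),
                        sessions = c("T0", "T1", "T2")) {
  measure <- match.arg(measure)
  pts <- sort(unique(scores$patient))
  m <- sapply(sessions, function(ses) {
    sub <- scores[scores$session == ses, ]
    sub[[measure]][match(pts, sub$patient)]
  })
  rownames(m) <- pts
  m
}
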