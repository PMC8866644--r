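#' Construct a montage from a channel table
#'
#' @param channels data.frame with columns \code{channel}, \code{source},
#'   \code{detector}, \code{separation}, \code{hemisphere}, \code{region}.
#' @return A validated \linkS4class{Montage}.
#' @export
montage <- function(channels) {
  channels$channel <- as.integer(channels$channel)
  channels <- channels[order(channels$channel), , drop = FALSE]
  rownames(channels) <- NULL
  new("Montage", channels = channels)
}

#' Default 26-channel language-area montage
#'
#' A symmetric idealization of a 26-channel layout formed from 12 sources and
#' 10 detectors at 3 cm separation over Broca, Wernicke and adjacent areas,
#' 13 channels per hemisphere. Channels 1-13 are left-hemisphere (channels
#' 1-5 Broca, 6-9 adjacent, 10-13 Wernicke); channels 14-26 mirror them on
#' the right. Source/detector 10-20 labels are plausible positions for such
#' a layout; real studies should supply their own montage via
#' [readMontage()].
#'
#' @param separation source-detector separation in cm (default 3).
#' @return A \linkS4class{Montage} with 26 channels.
#' @examples
#' m <- defaultMontage()
#' nChannels(m)
#' @export
defaultMontage <- function(separation = 3) {
  left_src <- c("F7", "F5", "FC5", "C5", "T7", "CP5")
  left_det <- c("FT7", "FC3", "C3", "TP7", "CP3")
  ## 13 source-detector pairings per hemisphere
  pair_idx <- cbind(
    src = c(1, 1, 2, 2, 3, 3, 3, 4, 4, 5, 5, 6, 6),
    det = c(1, 2, 2, 3, 1, 2, 3, 3, 5, 1, 4, 4, 5))
  region_left <- c(rep("broca", 5), rep("adjacent", 4), rep("wernicke", 4))
  mirror <- function(lab) chartr("357", "468", lab)
  ch <- data.frame(
    channel = 1:26,
    source = c(left_src[pair_idx[, "src"]], mirror(left_src[pair_idx[, "src"]])),
    detector = c(left_det[pair_idx[, "det"]], mirror(left_det[pair_idx[, "det"]])),
    separation = separation,
    hemisphere = rep(c("left", "right"), each = 13),
    region = rep(region_left, 2),
    stringsAsFactors = FALSE)
  montage(ch)
}

#' Channel table of a montage
#'
#' @param x A \linkS4class{Montage}.
#' @return The channel data.frame.
#' @export
channelTable <- function(x) {
  stopifnot(is(x, "Montage"))
  x@channels
}

#' Channels belonging to one hemisphere
#'
#' @param x A \linkS4class{Montage}.
#' @param hemisphere \code{"left"} or \code{"right"}.
#' @return Integer vector of channel ids.
#' @export
hemisphereChannels <- function(x, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  ch <- channelTable(x)
  ids <- ch$channel[ch$hemisphere == hemisphere]
  if (length(ids) == 0)
    stop("hemisphere '", hemisphere, "' has no channels in this montage")
  ids
}

#' Read / write a montage as a tab-separated table
#'
#' The on-disk format is a TSV with header columns \code{channel},
#' \code{source}, \code{detector}, \code{separation}, \code{hemisphere},
#' \code{region}.
#'
#' @param path file path.
#' @return \code{readMontage} returns a \linkS4class{Montage};
#'   \code{writeMontage} returns \code{path} invisibly.
#' @export
readMontage <- function(path) {
  if (!file.exists(path)) stop("montage file not found: ", path)
  montage(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname readMontage
#' @param x A \linkS4class{Montage} to write.
#' @export
writeMontage <- function(x, path) {
  utils::write.table(channelTable(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
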