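#' Construct a block design
#'
#' The default paradigm is 2 min of initial rest followed by six 30-s task
#' blocks alternating with six 30-s control blocks (task first), giving a
#' total duration of 480 s.
#'
#' @param rest_s initial rest in seconds.
#' @param n_blocks number of task blocks (an equal number of control blocks
#'   is interleaved unless \code{n_control} says otherwise).
#' @param block_s block length in seconds.
#' @param fs sampling rate in Hz.
#' @param n_control number of control blocks (default \code{n_blocks}).
#' @param stimulus_s duration each stimulus is displayed within a task block.
#' @return A \linkS4class{BlockDesign}.
#' @examples
#' d <- makeBlockDesign(120, 6, 30, fs = 3.91)
#' totalDuration(d)  # 480
#' @export
makeBlockDesign <- function(rest_s = 120, n_blocks = 6, block_s = 30, fs = 3.91,
                            n_control = n_blocks, stimulus_s = 2) {
  if (fs <= 0 || block_s <= 0 || n_blocks < 1 || rest_s < 0)
    stop("block design arguments must be positive (rest_s may be 0)")
  new("BlockDesign", initialRest = rest_s, nTaskBlocks = n_blocks,
      nControlBlocks = n_control, blockLength = block_s,
      stimulusDuration = min(stimulus_s, block_s), samplingRate = fs)
}

#' Total duration and sample count of a design
#'
#' @param design A \linkS4class{BlockDesign}.
#' @return \code{totalDuration}: seconds; \code{nSamples}: sample count
#'   (\code{floor(duration * fs)}).
#' @export
totalDuration <- function(design) {
  design@initialRest +
    (design@nTaskBlocks + design@nControlBlocks) * design@blockLength
}

#' @rdname totalDuration
#' @export
nSamples <- function(design) {
  as.integer(floor(totalDuration(design) * design@samplingRate))
}

block_indicator <- function(design, which = c("task", "control")) {
  which <- match.arg(which)
  n <- nSamples(design)
  t_sec <- (seq_len(n) - 1) / design@samplingRate
  ind <- numeric(n)
  n_pairs <- max(design@nTaskBlocks, design@nControlBlocks)
  for (b in seq_len(n_pairs)) {
    task_start <- design@initialRest + (2 * (b - 1)) * design@blockLength
    ctrl_start <- task_start + design@blockLength
    if (which == "task" && b <= design@nTaskBlocks)
      ind[t_sec >= task_start & t_sec < task_start + design@blockLength] <- 1
    if (which == "control" && b <= design@nControlBlocks)
      ind[t_sec >= ctrl_start & t_sec < ctrl_start + design@blockLength] <- 1
  }
  ind
}

#' Task and control boxcar indicators
#'
#' Binary indicators, one sample per time point, that are 1 inside
#' task (resp. control) blocks. Task blocks come first and the two
#' indicators tile the post-rest interval without overlap.
#'
#' @param design A \linkS4class{BlockDesign}.
#' @return Numeric 0/1 vector of length \code{nSamples(design)}.
#' @export
taskIndicator <- function(design) block_indicator(design, "task")

#' @rdname taskIndicator
#' @export
controlIndicator <- function(design) block_indicator(design, "control")
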