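#' @import methods
#' @importFrom stats approx convolve cor dgamma filter mad median pchisq
#'   pnorm pt qt quantile rbinom rnorm rpois runif sd var
NULL

#' Sampling rate accessor
#'
#' @param x An object carrying a sampling rate (a \linkS4class{RawIntensity},
#'   \linkS4class{HemoTimeSeries} or \linkS4class{BlockDesign}).
#' @return Sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Number of channels accessor
#'
#' @param x A \linkS4class{Montage}, \linkS4class{RawIntensity} or
#'   \linkS4class{HemoTimeSeries}.
#' @return Integer channel count.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Hemoglobin component accessors
#'
#' Extract the oxygenated, deoxygenated or total hemoglobin concentration
#' change series (time x channel, mol/L relative to baseline).
#'
#' @param x A \linkS4class{HemoTimeSeries}.
#' @return A numeric matrix, time in rows, channels in columns.
#' @export
setGeneric("oxyHb", function(x) standardGeneric("oxyHb"))

#' @rdname oxyHb
#' @export
setGeneric("deoxyHb", function(x) standardGeneric("deoxyHb"))

#' @rdname oxyHb
#' @export
setGeneric("totalHb", function(x) standardGeneric("totalHb"))
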