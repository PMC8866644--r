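## Central S4 containers for the pipeline. All time axes are in seconds,
## channel indices are 1-based and follow montage order, concentrations are
## mol/L changes relative to baseline.

#' Montage: channel geometry and labels
#'
#' A montage links each measurement channel (a source-detector optode pair)
#' to its 10-20 position labels, source-detector separation, hemisphere and
#' language-region assignment.
#'
#' @slot channels data.frame with columns \code{channel} (integer, 1-based,
#'   contiguous), \code{source}, \code{detector} (10-20 position codes),
#'   \code{separation} (cm), \code{hemisphere} (\code{"left"}/\code{"right"})
#'   and \code{region} (\code{"broca"}, \code{"wernicke"}, \code{"adjacent"}).
#' @seealso [defaultMontage()], [readMontage()]
#' @export
setClass("Montage", representation(channels = "data.frame"))

setValidity("Montage", function(object) {
  ch <- object@channels
  need <- c("channel", "source", "detector", "separation", "hemisphere", "region")
  if (!all(need %in% names(ch)))
    return(paste("montage table must have columns:", paste(need, collapse = ", ")))
  if (nrow(ch) < 1) return("montage has no channels")
  if (!identical(as.integer(ch$channel), seq_len(nrow(ch))))
    return("channel ids must be unique and contiguous from 1")
  if (any(ch$separation <= 0)) return("all separations must be > 0")
  if (!all(ch$hemisphere %in% c("left", "right")))
    return("hemisphere must be 'left' or 'right'")
  if (!all(ch$region %in% c("broca", "wernicke", "adjacent")))
    return("region must be 'broca', 'wernicke' or 'adjacent'")
  TRUE
})

#' Block-design paradigm description
#'
#' Describes a block paradigm: an initial rest period followed by task blocks
#' alternating with control blocks of equal length.
#'
#' @slot initialRest seconds of rest before the first task block.
#' @slot nTaskBlocks,nControlBlocks block counts; blocks alternate
#'   task-first.
#' @slot blockLength seconds per block.
#' @slot stimulusDuration seconds each stimulus is shown within a task block.
#' @slot samplingRate Hz.
#' @seealso [makeBlockDesign()]
#' @export
setClass("BlockDesign", representation(
  initialRest = "numeric", nTaskBlocks = "numeric", nControlBlocks = "numeric",
  blockLength = "numeric", stimulusDuration = "numeric", samplingRate = "numeric"))

setValidity("BlockDesign", function(object) {
  v <- c(object@initialRest, object@nTaskBlocks, object@nControlBlocks,
         object@blockLength, object@stimulusDuration, object@samplingRate)
  if (any(!is.finite(v))) return("all design fields must be finite")
  if (object@initialRest < 0) return("initialRest must be >= 0")
  if (object@nTaskBlocks < 1 || object@nControlBlocks < 0)
    return("need at least one task block")
  if (abs(object@nTaskBlocks - object@nControlBlocks) > 1)
    return("task and control blocks must alternate (counts differ by at most 1)")
  if (object@blockLength <= 0 || object@samplingRate <= 0 ||
      object@stimulusDuration <= 0)
    return("durations and sampling rate must be > 0")
  TRUE
})

#' Raw two-wavelength optical intensities
#'
#' Light intensities as emitted by a continuous-wave fNIRS instrument, one
#' series per channel and wavelength, plus the baseline intensities used as
#' the optical-density reference.
#'
#' @slot samplingRate Hz.
#' @slot wavelengths numeric(2), nm (default 760 and 850).
#' @slot data numeric array time x channel x wavelength; strictly positive.
#' @slot baseline matrix channel x wavelength of baseline intensities I0.
#' @export
setClass("RawIntensity", representation(
  samplingRate = "numeric", wavelengths = "numeric",
  data = "array", baseline = "matrix"))

setValidity("RawIntensity", function(object) {
  d <- dim(object@data)
  if (length(d) != 3) return("data must be a time x channel x wavelength array")
  if (length(object@wavelengths) != d[3])
    return("wavelengths length must match third array dimension")
  if (!identical(dim(object@baseline), d[2:3]))
    return("baseline must be channel x wavelength")
  if (any(object@data <= 0) || any(object@baseline <= 0))
    return("all intensities must be strictly positive")
  if (object@samplingRate <= 0) return("samplingRate must be > 0")
  TRUE
})

#' Hemoglobin concentration-change time series
#'
#' Per-channel oxygenated and deoxygenated hemoglobin concentration changes
#' (mol/L relative to baseline). Total hemoglobin is their sum and is exposed
#' through [totalHb()] so the identity holds by construction.
#'
#' @slot samplingRate Hz.
#' @slot oxy,deoxy numeric matrices, time x channel.
#' @export
setClass("HemoTimeSeries", representation(
  samplingRate = "numeric", oxy = "matrix", deoxy = "matrix"))

setValidity("HemoTimeSeries", function(object) {
  if (!identical(dim(object@oxy), dim(object@deoxy)))
    return("oxy and deoxy must have identical dimensions")
  if (object@samplingRate <= 0) return("samplingRate must be > 0")
  TRUE
})

#' Optical parameters for the modified Beer-Lambert law
#'
#' @slot wavelengths numeric(2), nm.
#' @slot dpf numeric(2), differential path-length factor per wavelength.
#' @slot extinction 2 x 2 matrix of molar extinction coefficients
#'   (cm^-1 (mol/L)^-1); rows are wavelengths, columns \code{oxy}, \code{deoxy}.
#' @slot tableId identifier of the extinction compilation in use.
#' @seealso [opticsParams()]
#' @export
setClass("OpticsParams", representation(
  wavelengths = "numeric", dpf = "numeric", extinction = "matrix",
  tableId = "character"))

setValidity("OpticsParams", function(object) {
  if (length(object@wavelengths) != 2 || length(object@dpf) != 2)
    return("exactly two wavelengths with one DPF each are supported")
  if (any(object@dpf <= 0)) return("DPF must be > 0")
  if (!identical(dim(object@extinction), c(2L, 2L)))
    return("extinction must be a 2x2 matrix (wavelength x species)")
  if (abs(det(object@extinction)) < .Machine$double.eps * 100)
    return("extinction matrix is singular: species are not separable")
  TRUE
})

#' Canonical HRF parameters
#'
#' Parameters of the double-gamma canonical hemodynamic response function.
#' Each gamma is parameterized so its mode falls at the stated delay.
#'
#' @slot peakDelay,undershootDelay seconds.
#' @slot peakDispersion,undershootDispersion dimensionless width scales.
#' @slot undershootRatio relative undershoot amplitude.
#' @slot kernelLength seconds of kernel support.
#' @seealso [hrfParams()], [canonicalHrf()]
#' @export
setClass("HrfParams", representation(
  peakDelay = "numeric", undershootDelay = "numeric",
  peakDispersion = "numeric", undershootDispersion = "numeric",
  undershootRatio = "numeric", kernelLength = "numeric"))

setValidity("HrfParams", function(object) {
  v <- c(object@peakDelay, object@undershootDelay, object@peakDispersion,
         object@undershootDispersion, object@kernelLength)
  if (any(v <= 0)) return("all HRF delays, dispersions and length must be > 0")
  if (object@undershootRatio < 0) return("undershootRatio must be >= 0")
  TRUE
})

#' Ground-truth effect specification for the cohort simulator
#'
#' Defines what the forward simulator injects: per-channel activation
#' amplitudes, AR(1) noise, physiological sinusoids, drift, optical-domain
#' spikes, and a modular latent correlation structure.
#'
#' @slot betaTrue numeric, per-channel activation amplitude (mol/L at unit
#'   regressor value); recycled if scalar.
#' @slot ar AR(1) coefficient of the channel noise, |ar| < 1.
#' @slot innovationSd innovation standard deviation (mol/L).
#' @slot physio data.frame(freq, amplitude): sinusoidal physiological
#'   confounds (Hz, mol/L).
#' @slot driftSlope linear drift slope (mol/L per second).
#' @slot spikeRate motion-spike rate (events per minute, optical domain).
#' @slot spikeMagnitude spike magnitude in optical-density units.
#' @slot modules list of integer channel sets with latent within-module
#'   correlation \code{rWithin}; disjoint.
#' @slot rWithin,rBetween latent correlation targets, 0 <= rBetween <=
#'   rWithin < 1.
#' @slot deoxyGamma anti-correlation factor of the surrogate deoxyHb series.
#' @slot deoxyNoiseSd independent deoxyHb noise (mol/L).
#' @seealso [effectSpec()], [simulateSubject()]
#' @export
setClass("EffectSpec", representation(
  betaTrue = "numeric", ar = "numeric", innovationSd = "numeric",
  physio = "data.frame", driftSlope = "numeric",
  spikeRate = "numeric", spikeMagnitude = "numeric",
  modules = "list", rWithin = "numeric", rBetween = "numeric",
  deoxyGamma = "numeric", deoxyNoiseSd = "numeric"))

setValidity("EffectSpec", function(object) {
  if (abs(object@ar) >= 1) return("|AR(1) coefficient| must be < 1")
  if (object@innovationSd < 0 || object@deoxyNoiseSd < 0)
    return("noise SDs must be >= 0")
  if (object@rBetween < 0 || any(object@rWithin >= 1) ||
      any(object@rBetween > object@rWithin))
    return("need 0 <= rBetween <= rWithin < 1")
  if (length(object@modules) > 1) {
    all_ch <- unlist(object@modules)
    if (anyDuplicated(all_ch)) return("module channel sets must be disjoint")
  }
  if (nrow(object@physio) > 0 &&
      !all(c("freq", "amplitude") %in% names(object@physio)))
    return("physio must have columns freq, amplitude")
  TRUE
})

#' Artifact mask
#'
#' Per-sample flags plus the flagged segments with their reason, produced by
#' [detectArtifacts()].
#'
#' @slot flags logical matrix, time x channel.
#' @slot segments data.frame(channel, start_s, end_s, reason) with reason in
#'   \code{"spike"}/\code{"discontinuity"}; sorted, non-overlapping per channel.
#' @export
setClass("ArtifactMask", representation(
  flags = "matrix", segments = "data.frame"))

setValidity("ArtifactMask", function(object) {
  if (!is.logical(object@flags)) return("flags must be logical")
  seg <- object@segments
  need <- c("channel", "start_s", "end_s", "reason")
  if (nrow(seg) > 0) {
    if (!all(need %in% names(seg)))
      return(paste("segments needs columns:", paste(need, collapse = ", ")))
    if (any(seg$end_s < seg$start_s)) return("segment end before start")
    if (!all(seg$reason %in% c("spike", "discontinuity")))
      return("segment reason must be 'spike' or 'discontinuity'")
  }
  TRUE
})

#' Per-channel GLM activation result
#'
#' @slot table data.frame(channel, beta, t, p) per channel.
#' @slot effDf Satterthwaite effective degrees of freedom of the fit.
#' @slot hotspotChannel channel id with the largest |t| among channels
#'   passing the (adaptively relaxed) p threshold.
#' @slot alphaUsed the significance level at which the hotspot was found.
#' @seealso [activationMap()], [selectHotspot()]
#' @export
setClass("ActivationResult", representation(
  table = "data.frame", effDf = "numeric",
  hotspotChannel = "integer", alphaUsed = "numeric"))

setValidity("ActivationResult", function(object) {
  tb <- object@table
  if (!all(c("channel", "beta", "t", "p") %in% names(tb)))
    return("table needs columns channel, beta, t, p")
  if (any(tb$p < 0 | tb$p > 1, na.rm = TRUE)) return("p must lie in [0, 1]")
  TRUE
})

#' Channel-pair functional connectivity matrix
#'
#' Symmetric Pearson correlation matrix over channels together with its
#' Fisher z-transform; the diagonal is masked (NA).
#'
#' @slot r,z numeric matrices, channel x channel; \code{z = atanh(r)}.
#' @slot subject,session identifiers.
#' @slot window correlation window used (\code{"full"} or
#'   \code{"task_blocks"}).
#' @seealso [correlationMatrix()]
#' @export
setClass("ConnectivityMatrix", representation(
  r = "matrix", z = "matrix", subject = "character", session = "character",
  window = "character"))

setValidity("ConnectivityMatrix", function(object) {
  if (!identical(dim(object@r), dim(object@z)) ||
      nrow(object@r) != ncol(object@r))
    return("r and z must be square matrices of identical dimension")
  off <- object@r[upper.tri(object@r)]
  if (any(abs(off) > 1 + 1e-12, na.rm = TRUE))
    return("off-diagonal correlations must lie in [-1, 1]")
  asym <- abs(object@r - t(object@r))
  if (any(is.finite(asym)) && max(asym, na.rm = TRUE) > 1e-10)
    return("correlation matrix must be symmetric")
  TRUE
})

#' Hemispheric metric-vs-sparsity profile
#'
#' Clustering coefficient and global efficiency of the hemisphere-restricted
#' binary graph at each sparsity level, one row per subject.
#'
#' @slot hemisphere \code{"left"}, \code{"right"} or \code{"whole"}.
#' @slot session session label.
#' @slot sparsity the sparsity grid (strictly increasing, in [0, 1]).
#' @slot clustering,efficiency numeric matrices subject x sparsity.
#' @slot subjects subject identifiers (row order).
#' @seealso [sparsityProfile()], [compareProfiles()]
#' @export
setClass("NetworkProfile", representation(
  hemisphere = "character", session = "character", sparsity = "numeric",
  clustering = "matrix", efficiency = "matrix", subjects = "character"))

setValidity("NetworkProfile", function(object) {
  g <- object@sparsity
  if (any(g < 0 | g > 1) || is.unsorted(g, strictly = TRUE))
    return("sparsity grid must be strictly increasing within [0, 1]")
  if (!identical(dim(object@clustering), dim(object@efficiency)))
    return("clustering and efficiency must share dimensions")
  if (ncol(object@clustering) != length(g))
    return("one metric column per sparsity grid point required")
  TRUE
})

#' Pipeline configuration
#'
#' Every tunable of the pipeline in one validated object; see
#' [pipelineConfig()] for defaults and units.
#'
#' @slot samplingRate Hz (simulation and CSV-less contexts).
#' @slot lowHz,highHz band-pass cut-offs (Hz).
#' @slot dpf differential path-length factors at the two wavelengths.
#' @slot extinctionTable extinction compilation id.
#' @slot hrf \linkS4class{HrfParams}.
#' @slot dctCutoff DCT drift-filter cutoff period (s).
#' @slot hotspotAlpha0,hotspotStep adaptive hotspot threshold start and step.
#' @slot strongZ strong-connectivity threshold on mean Fisher z.
#' @slot sparsityGrid strictly increasing grid within [0, 1].
#' @slot networkAlpha per-sparsity-point significance level.
#' @slot artifactSpikeZ,artifactJumpZ,artifactWindowS artifact detection
#'   thresholds (robust SD units) and window (s).
#' @slot artifactsEnabled logical; disable for strict filter-only runs.
#' @slot correlationWindow \code{"full"} or \code{"task_blocks"}.
#' @slot seed integer master seed.
#' @export
setClass("PipelineConfig", representation(
  samplingRate = "numeric", lowHz = "numeric", highHz = "numeric",
  dpf = "numeric", extinctionTable = "character", hrf = "HrfParams",
  dctCutoff = "numeric", hotspotAlpha0 = "numeric", hotspotStep = "numeric",
  strongZ = "numeric", sparsityGrid = "numeric", networkAlpha = "numeric",
  artifactSpikeZ = "numeric", artifactJumpZ = "numeric",
  artifactWindowS = "numeric", artifactsEnabled = "logical",
  correlationWindow = "character", seed = "integer"))

setValidity("PipelineConfig", function(object) {
  if (!(0 < object@lowHz && object@lowHz < object@highHz &&
        object@highHz < object@samplingRate / 2))
    return("need 0 < lowHz < highHz < samplingRate/2")
  if (!(object@hotspotAlpha0 > 0 && object@hotspotAlpha0 < 1))
    return("hotspotAlpha0 must lie in (0, 1)")
  if (object@hotspotStep <= 0) return("hotspotStep must be > 0")
  g <- object@sparsityGrid
  if (length(g) == 0) return("sparsity grid must be non-empty")
  if (any(g < 0 | g > 1) || is.unsorted(g, strictly = TRUE))
    return("sparsity grid must be strictly increasing within [0, 1]")
  if (!object@correlationWindow %in% c("full", "task_blocks"))
    return("correlationWindow must be 'full' or 'task_blocks'")
  TRUE
})

## ------------------------------------------------------------------ methods

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "RawIntensity", function(x) x@samplingRate)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "HemoTimeSeries", function(x) x@samplingRate)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "BlockDesign", function(x) x@samplingRate)

#' @rdname nChannels
#' @export
setMethod("nChannels", "Montage", function(x) nrow(x@channels))
#' @rdname nChannels
#' @export
setMethod("nChannels", "RawIntensity", function(x) dim(x@data)[2])
#' @rdname nChannels
#' @export
setMethod("nChannels", "HemoTimeSeries", function(x) ncol(x@oxy))

#' @rdname oxyHb
#' @export
setMethod("oxyHb", "HemoTimeSeries", function(x) x@oxy)
#' @rdname oxyHb
#' @export
setMethod("deoxyHb", "HemoTimeSeries", function(x) x@deoxy)
#' @rdname oxyHb
#' @export
setMethod("totalHb", "HemoTimeSeries", function(x) x@oxy + x@deoxy)

setMethod("show", "Montage", function(object) {
  ch <- object@channels
  cat("Montage:", nrow(ch), "channels;",
      sum(ch$hemisphere == "left"), "left /",
      sum(ch$hemisphere == "right"), "right\n")
  cat("  regions:", paste(sprintf("%s=%d", names(table(ch$region)),
                                  table(ch$region)), collapse = ", "), "\n")
})

setMethod("show", "BlockDesign", function(object) {
  cat(sprintf(
    "BlockDesign: %gs rest + %d task / %d control blocks of %gs @ %g Hz (total %gs)\n",
    object@initialRest, object@nTaskBlocks, object@nControlBlocks,
    object@blockLength, object@samplingRate, totalDuration(object)))
})

setMethod("show", "HemoTimeSeries", function(object) {
  cat(sprintf("HemoTimeSeries: %d samples x %d channels @ %g Hz\n",
              nrow(object@oxy), ncol(object@oxy), object@samplingRate))
})

setMethod("show", "RawIntensity", function(object) {
  d <- dim(object@data)
  cat(sprintf("RawIntensity: %d samples x %d channels x %d wavelengths (%s nm) @ %g Hz\n",
              d[1], d[2], d[3], paste(object@wavelengths, collapse = "/"),
              object@samplingRate))
})

setMethod("show", "ActivationResult", function(object) {
  cat(sprintf("ActivationResult: %d channels, eff. df %.1f\n",
              nrow(object@table), object@effDf))
  cat(sprintf("  hotspot: channel %d (alpha used %.3f)\n",
              object@hotspotChannel, object@alphaUsed))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix: %d x %d [subject %s, session %s, window %s]\n",
              nrow(object@r), ncol(object@r), object@subject, object@session,
              object@window))
})

setMethod("show", "NetworkProfile", function(object) {
  cat(sprintf("NetworkProfile: %s hemisphere, session %s, %d subjects x %d sparsity points\n",
              object@hemisphere, object@session, nrow(object@clustering),
              length(object@sparsity)))
})
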