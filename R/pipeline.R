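## End-to-end pipeline: preprocess -> activation -> connectivity -> network
## -> group statistics, with structured stage logging to stderr and a
## machine-readable results document. Given a fixed (config, cohort) pair
## the whole run is deterministic.

pipeline_log <- function(stage, ...) {
  if (isTRUE(getOption("nirsnet.quiet", FALSE))) return(invisible())
  message(sprintf("[nirsnet:%s] %s", stage, sprintf(...)))
}

#' Pipeline configuration with documented defaults
#'
#' Defaults: 3.91 Hz sampling (typical of multiplexed LED arrays of this
#' source count; the rate is always a parameter, never assumed), band-pass
#' 0.01-0.2 Hz, DPF 7.25/7.38 at 760/850 nm per the standard compilation
#' choice (see [opticsParams()]), canonical HRF, 128 s DCT drift cutoff,
#' hotspot threshold starting at 0.05 with 0.001 increments, strong-edge
#' threshold z = 1.0, sparsity grid 0.01..1.00 in 0.01 steps, per-point
#' network alpha 0.1, artifact thresholds 5 robust SDs over a 2 s window.
#'
#' @param samplingRate Hz.
#' @param lowHz,highHz band-pass cut-offs (Hz).
#' @param dpf numeric(2) differential path-length factors.
#' @param extinctionTable extinction compilation id.
#' @param hrf An \linkS4class{HrfParams}.
#' @param dctCutoff DCT cutoff (s).
#' @param hotspotAlpha0,hotspotStep adaptive hotspot threshold parameters.
#' @param strongZ strong-connectivity threshold on mean z.
#' @param sparsityGrid sparsity grid.
#' @param networkAlpha per-point significance level for profile comparison.
#' @param artifactSpikeZ,artifactJumpZ,artifactWindowS artifact detection
#'   parameters.
#' @param artifactsEnabled disable for strict filter-only parity runs.
#' @param correlationWindow \code{"full"} or \code{"task_blocks"}.
#' @param seed integer master seed.
#' @return A validated \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(samplingRate = 3.91, lowHz = 0.01, highHz = 0.2,
                           dpf = c(7.25, 6.38), extinctionTable = "prahl",
                           hrf = hrfParams(), dctCutoff = 128,
                           hotspotAlpha0 = 0.05, hotspotStep = 0.001,
                           strongZ = 1.0,
                           sparsityGrid = seq(0.01, 1, by = 0.01),
                           networkAlpha = 0.1,
                           artifactSpikeZ = 5, artifactJumpZ = 5,
                           artifactWindowS = 2, artifactsEnabled = TRUE,
                           correlationWindow = "full", seed = 1L) {
  new("PipelineConfig", samplingRate = samplingRate, lowHz = lowHz,
      highHz = highHz, dpf = dpf, extinctionTable = extinctionTable,
      hrf = hrf, dctCutoff = dctCutoff, hotspotAlpha0 = hotspotAlpha0,
      hotspotStep = hotspotStep, strongZ = strongZ,
      sparsityGrid = sparsityGrid, networkAlpha = networkAlpha,
      artifactSpikeZ = artifactSpikeZ, artifactJumpZ = artifactJumpZ,
      artifactWindowS = artifactWindowS, artifactsEnabled = artifactsEnabled,
      correlationWindow = correlationWindow, seed = as.integer(seed))
}

config_to_list <- function(config) {
  h <- config@hrf
  list(samplingRate = config@samplingRate, lowHz = config@lowHz,
       highHz = config@highHz, dpf = config@dpf,
       extinctionTable = config@extinctionTable,
       hrf = list(peakDelay = h@peakDelay, undershootDelay = h@undershootDelay,
                  peakDispersion = h@peakDispersion,
                  undershootDispersion = h@undershootDispersion,
                  undershootRatio = h@undershootRatio,
                  kernelLength = h@kernelLength),
       dctCutoff = config@dctCutoff, hotspotAlpha0 = config@hotspotAlpha0,
       hotspotStep = config@hotspotStep, strongZ = config@strongZ,
       sparsityGrid = config@sparsityGrid, networkAlpha = config@networkAlpha,
       artifactSpikeZ = config@artifactSpikeZ,
       artifactJumpZ = config@artifactJumpZ,
       artifactWindowS = config@artifactWindowS,
       artifactsEnabled = config@artifactsEnabled,
       correlationWindow = config@correlationWindow, seed = config@seed)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return \code{readPipelineConfig} returns a
#'   \linkS4class{PipelineConfig}; \code{writePipelineConfig} returns
#'   \code{path} invisibly.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  hrf <- if (!is.null(y$hrf)) do.call(hrfParams, y$hrf) else hrfParams()
  y$hrf <- NULL
  y$sparsityGrid <- as.numeric(unlist(y$sparsityGrid))
  y$dpf <- as.numeric(unlist(y$dpf))
  do.call(pipelineConfig, c(y, list(hrf = hrf)))
}

#' @rdname readPipelineConfig
#' @param config A \linkS4class{PipelineConfig}.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

preprocess_recording <- function(raw, montage, config) {
  optics <- suppressMessages(
    opticsParams(raw@wavelengths, config@dpf, config@extinctionTable))
  od <- odFromIntensity(raw)
  hemo <- hemoglobinFromOD(od, optics,
                           separations = channelTable(montage)$separation,
                           fs = samplingRate(raw))
  if (config@artifactsEnabled) {
    mask <- detectArtifacts(hemo, config@artifactSpikeZ, config@artifactJumpZ,
                            config@artifactWindowS)
    hemo <- repairArtifacts(hemo, mask)
  }
  bandpassFilter(hemo, config@lowHz, config@highHz)
}

#' Run the full pipeline on a cohort
#'
#' Executes preprocess (MBLL conversion, artifact repair, band-pass) ->
#' per-channel GLM activation with hotspot selection -> Fisher-z
#' connectivity with per-session group averages and strong edges ->
#' hemispheric sparsity-profiled network metrics with between-session
#' comparisons -> clinical group statistics (when scores are supplied).
#' Every stage is logged with its parameters; the run is a pure function of
#' (config, cohort, clinical).
#'
#' @param config A \linkS4class{PipelineConfig}.
#' @param cohort a \code{"nirsCohort"} (from [simulateCohort()] or
#'   assembled from disk recordings with the same structure).
#' @param clinical optional data.frame of clinical scores
#'   (see [loadClinicalScores()]); group tests refuse cohorts of fewer than
#'   two subjects.
#' @return list of class \code{"nirsReport"}: \code{hotspots} (data.frame),
#'   \code{activation} (per subject-session \linkS4class{ActivationResult}),
#'   \code{connectivity} (per-session mean-z matrices and strong-edge
#'   tables, the connectivity-figure specification), \code{networks}
#'   (per-hemisphere \linkS4class{NetworkProfile}s and session-pair
#'   comparisons, the metric-vs-sparsity figure specification),
#'   \code{clinicalStats}, \code{config}, \code{seed}.
#' @export
runPipeline <- function(config, cohort, clinical = NULL) {
  stopifnot(is(config, "PipelineConfig"))
  if (length(cohort$subjects) < 1 || length(cohort$sessions) < 1)
    stop("cohort must have at least one subject and one session")
  montage <- cohort$montage
  design <- cohort$design
  sessions <- cohort$sessions
  subjects <- cohort$subjects
  pipeline_log("start", "%d subjects x %d sessions, seed %d",
               length(subjects), length(sessions), config@seed)

  ## stage 1-2: preprocessing + activation
  kernel <- canonicalHrf(design@samplingRate, config@hrf)
  n <- nSamples(design)
  X <- buildDesignMatrix(design, kernel, config@dctCutoff, n = n)
  op <- glmOperator(X, kernel)
  pipeline_log("activation", "design: %d samples, %d columns, eff. df %.1f",
               n, ncol(X), op$effDf)
  processed <- list()
  activation <- list()
  hotspots <- NULL
  for (s in subjects) {
    processed[[s]] <- list()
    activation[[s]] <- list()
    for (ses in sessions) {
      rec <- cohort$recordings[[s]][[ses]]
      hemo <- tryCatch(
        preprocess_recording(rec$raw, montage, config),
        error = function(e) stop("stage preprocess failed for subject ", s,
                                 " session ", ses, ": ", conditionMessage(e)))
      processed[[s]][[ses]] <- hemo
      act <- tryCatch(
        activationMap(hemo, design, config@hrf, config@dctCutoff,
                      config@hotspotAlpha0, config@hotspotStep, op = op),
        error = function(e) stop("stage activation failed for subject ", s,
                                 " session ", ses, ": ", conditionMessage(e)))
      activation[[s]][[ses]] <- act
      hotspots <- rbind(hotspots, data.frame(
        subject = s, session = ses, channel = act@hotspotChannel,
        alphaUsed = act@alphaUsed,
        t = act@table$t[act@hotspotChannel],
        deactivation = act@table$t[act@hotspotChannel] < 0))
    }
  }
  if (any(hotspots$deactivation))
    pipeline_log("activation",
                 "note: %d hotspot(s) have negative t (|t| rule can select deactivation)",
                 sum(hotspots$deactivation))

  ## stage 3: connectivity
  connectivity <- list()
  for (ses in sessions) {
    mats <- lapply(subjects, function(s)
      correlationMatrix(processed[[s]][[ses]], config@correlationWindow,
                        design, subject = s, session = ses))
    names(mats) <- subjects
    meanZ <- groupAverage(mats)
    edges <- strongEdges(meanZ, config@strongZ)
    pipeline_log("connectivity", "session %s: %d strong edges at z > %g",
                 ses, nrow(edges), config@strongZ)
    connectivity[[ses]] <- list(matrices = mats, meanZ = meanZ,
                                strongEdges = edges)
  }

  ## stage 4: hemispheric networks over sparsity
  networks <- list(profiles = list(), comparisons = list())
  for (hemi in c("left", "right")) {
    for (ses in sessions) {
      networks$profiles[[hemi]][[ses]] <- networkProfile(
        connectivity[[ses]]$matrices, montage, hemi, ses,
        grid = config@sparsityGrid)
    }
  }
  if (length(subjects) >= 4 && length(sessions) >= 2) {
    pairs <- cbind(sessions[-length(sessions)], sessions[-1])
    for (hemi in c("left", "right")) {
      for (i in seq_len(nrow(pairs))) {
        a <- pairs[i, 1]; b <- pairs[i, 2]
        for (metric in c("clustering", "efficiency")) {
          cmp <- compareProfiles(networks$profiles[[hemi]][[a]],
                                 networks$profiles[[hemi]][[b]],
                                 metric = metric, alpha = config@networkAlpha)
          key <- sprintf("%s_%s_vs_%s_%s", hemi, a, b, metric)
          networks$comparisons[[key]] <- cmp
          if (nrow(cmp$ranges))
            pipeline_log("network", "%s: %d significant range(s), e.g. [%g, %g]",
                         key, nrow(cmp$ranges), cmp$ranges$start[1],
                         cmp$ranges$end[1])
        }
      }
    }
  } else {
    pipeline_log("network", "fewer than 4 subjects or 2 sessions: profile comparison skipped")
  }

  ## stage 5: clinical group statistics
  clinicalStats <- NULL
  if (!is.null(clinical)) {
    if (length(unique(clinical$patient)) < 2)
      stop("stage stats refused: fewer than 2 subjects (n too small)")
    clinicalStats <- list()
    for (measure in intersect(c("AQ", "LQ"), names(clinical))) {
      m <- scoreMatrix(clinical, measure, sessions = intersect(
        c("T0", "T1", "T2"), unique(clinical$session)))
      res <- list(friedman = friedmanRankTest(m))
      for (i in seq_len(ncol(m) - 1)) {
        lab <- paste0(colnames(m)[i], "_vs_", colnames(m)[i + 1])
        res[[lab]] <- wilcoxonSignedRank(m[, i], m[, i + 1])
      }
      clinicalStats[[measure]] <- res
      pipeline_log("stats", "%s: Friedman p = %.3f", measure,
                   res$friedman$p.value)
    }
  }

  structure(list(hotspots = hotspots, activation = activation,
                 connectivity = connectivity, networks = networks,
                 clinicalStats = clinicalStats,
                 config = config_to_list(config), seed = config@seed),
            class = "nirsReport")
}

#' @export
print.nirsReport <- function(x, ...) {
  cat("nirsnet pipeline report\n")
  cat("  hotspots:\n")
  print(x$hotspots[, c("subject", "session", "channel", "alphaUsed")])
  for (ses in names(x$connectivity))
    cat(sprintf("  %s: %d strong edges\n", ses,
                nrow(x$connectivity[[ses]]$strongEdges)))
  ncmp <- length(x$networks$comparisons)
  if (ncmp) {
    nsig <- sum(vapply(x$networks$comparisons,
                       function(c) nrow(c$ranges) > 0, logical(1)))
    cat(sprintf("  network comparisons: %d, %d with significant ranges\n",
                ncmp, nsig))
  }
  invisible(x)
}

#' Write a machine-readable results document
#'
#' Writes \code{results.json} (hotspots, strong edges, significant network
#' ranges, clinical statistics, full config echo and seed) plus per-stage
#' TSV tables (activation per subject-session, strong edges and
#' metric-vs-sparsity curves per session). Output is deterministic: rerun
#' with the same seed and inputs, the files are byte-identical.
#'
#' @param report an object from [runPipeline()].
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(report$activation))
    for (ses in names(report$activation[[s]]))
      utils::write.table(report$activation[[s]][[ses]]@table,
                         file.path(dir, sprintf("activation_%s_%s.tsv", s, ses)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  edges_json <- list()
  for (ses in names(report$connectivity)) {
    e <- report$connectivity[[ses]]$strongEdges
    utils::write.table(e, file.path(dir, sprintf("strong_edges_%s.tsv", ses)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    edges_json[[ses]] <- e
  }
  curves <- NULL
  for (hemi in names(report$networks$profiles))
    for (ses in names(report$networks$profiles[[hemi]])) {
      pr <- report$networks$profiles[[hemi]][[ses]]
      curves <- rbind(curves, data.frame(
        hemisphere = hemi, session = ses, sparsity = pr@sparsity,
        clustering = colMeans(pr@clustering),
        efficiency = colMeans(pr@efficiency)))
    }
  if (!is.null(curves))
    utils::write.table(curves, file.path(dir, "network_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  ranges <- lapply(report$networks$comparisons, `[[`, "ranges")
  stats_json <- NULL
  if (!is.null(report$clinicalStats))
    stats_json <- lapply(report$clinicalStats, function(res)
      lapply(res, function(h)
        list(statistic = unname(h$statistic), p = h$p.value)))
  jsonlite::write_json(
    list(seed = report$seed, config = report$config,
         hotspots = report$hotspots, strongEdges = edges_json,
         significantRanges = ranges, clinicalStats = stats_json),
    file.path(dir, "results.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null")
  invisible(dir)
}
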