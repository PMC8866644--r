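## Forward simulator for block-design fNIRS cohorts. Every stage of the
## analysis has a recoverable ground truth: activation amplitudes, the latent
## inter-channel correlation, the noise model and all seeds are known.

#' Ground-truth effect specification
#'
#' Builds the effect specification the simulator injects into a recording.
#' Defaults emulate a task-evoked oxyHb response of realistic micromolar
#' scale on top of AR(1) channel noise, the three standard physiological
#' confounds (cardiac ~1 Hz, respiration ~0.25 Hz, Mayer waves ~0.1 Hz; each
#' with a channel-specific random phase), a slow linear drift and sparse
#' motion spikes in the optical domain.
#'
#' The latent correlation structure is modular: by default one module per
#' hemisphere-region block of the montage (broca/wernicke/adjacent x
#' left/right), with within-module correlation \code{rWithin} (recycled and
#' named per module, so individual modules can be retargeted) and
#' between-module correlation \code{rBetween}.
#'
#' @param montage A \linkS4class{Montage}; defines channel count and the
#'   default module partition.
#' @param betaTrue per-channel activation amplitude in mol/L per unit of the
#'   convolved task regressor (scalar recycled).
#' @param ar AR(1) coefficient of the channel noise.
#' @param innovationSd innovation SD of the channel noise (mol/L).
#' @param physio data.frame(freq, amplitude) of sinusoidal confounds.
#' @param driftSlope linear drift, mol/L per second.
#' @param spikeRate expected motion spikes per minute.
#' @param spikeMagnitude spike size in optical-density units.
#' @param modules list of integer channel sets (named); default the
#'   hemisphere-region blocks of \code{montage}.
#' @param rWithin within-module latent correlation target(s), recycled to
#'   one value per module.
#' @param rBetween between-module latent correlation target.
#' @param deoxyGamma anti-correlation factor of the surrogate deoxyHb.
#' @param deoxyNoiseSd independent deoxyHb noise SD (mol/L).
#' @return A validated \linkS4class{EffectSpec}.
#' @export
effectSpec <- function(montage = defaultMontage(),
                       betaTrue = 0,
                       ar = 0.3, innovationSd = 2e-7,
                       physio = data.frame(
                         freq = c(1.0, 0.25, 0.1),
                         amplitude = c(1e-7, 8e-8, 5e-8)),
                       driftSlope = 4e-10,
                       spikeRate = 0.5, spikeMagnitude = 0.05,
                       modules = NULL,
                       rWithin = 0.3, rBetween = 0.1,
                       deoxyGamma = 0.3, deoxyNoiseSd = 5e-8) {
  n_ch <- nChannels(montage)
  if (is.null(modules)) {
    ch <- channelTable(montage)
    modules <- split(ch$channel, paste(ch$hemisphere, ch$region, sep = "_"))
  }
  rWithin <- rep_len(rWithin, length(modules))
  names(rWithin) <- names(modules)
  if (rBetween > min(rWithin))
    stop("rBetween must not exceed any module's rWithin")
  new("EffectSpec",
      betaTrue = rep_len(betaTrue, n_ch), ar = ar,
      innovationSd = innovationSd, physio = physio, driftSlope = driftSlope,
      spikeRate = spikeRate, spikeMagnitude = spikeMagnitude,
      modules = modules, rWithin = rWithin, rBetween = rBetween,
      deoxyGamma = deoxyGamma, deoxyNoiseSd = deoxyNoiseSd)
}

#' Modify an effect specification
#'
#' Replace named slots of an \linkS4class{EffectSpec}, revalidating the
#' result. Used for per-session overrides in [simulateCohort()].
#'
#' @param spec An \linkS4class{EffectSpec}.
#' @param ... named slot replacements (e.g. \code{rWithin = c(...)}).
#' @return The modified, validated spec.
#' @export
modifyEffectSpec <- function(spec, ...) {
  mods <- list(...)
  bad <- setdiff(names(mods), slotNames("EffectSpec"))
  if (length(bad)) stop("unknown EffectSpec field(s): ", paste(bad, collapse = ", "))
  for (nm in names(mods)) {
    v <- mods[[nm]]
    if (nm == "rWithin") {
      v <- rep_len(v, length(spec@modules))
      names(v) <- names(spec@modules)
    }
    slot(spec, nm) <- v
  }
  validObject(spec)
  spec
}

#' Latent inter-channel correlation matrix
#'
#' The target correlation matrix implied by an effect specification:
#' \code{rWithin[m]} inside module m, \code{rBetween} between modules, unit
#' diagonal. If the construction is indefinite it is repaired to the nearest
#' positive-semidefinite correlation matrix (eigenvalue clipping, logged);
#' repairs that would move entries by more than \code{repairTol} raise an
#' error.
#'
#' @param spec An \linkS4class{EffectSpec}.
#' @param nChannels channel count.
#' @param repairTol maximum admissible entrywise repair distance.
#' @return Symmetric PSD correlation matrix with unit diagonal.
#' @export
latentCovariance <- function(spec, nChannels, repairTol = 0.05) {
  if (length(spec@modules) &&
      max(unlist(spec@modules)) > nChannels)
    stop("module channel sets must be subsets of 1..", nChannels)
  R <- matrix(spec@rBetween, nChannels, nChannels)
  for (i in seq_along(spec@modules)) {
    m <- spec@modules[[i]]
    R[m, m] <- spec@rWithin[i]
  }
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    vals <- pmax(ev$values, 0)
    R2 <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    d <- sqrt(diag(R2))
    R2 <- R2 / outer(d, d)
    if (max(abs(R2 - R)) > repairTol)
      stop("latent correlation is indefinite beyond repair tolerance; ",
           "offending smallest eigenvalue ", signif(min(ev$values), 3))
    message("latent correlation repaired to nearest PSD (max entry change ",
            signif(max(abs(R2 - R)), 3), ")")
    R <- R2
  }
  R
}

conv_causal <- function(x, k) {
  stats::convolve(x, rev(k), type = "open")[seq_along(x)]
}

#' Simulate one subject's recording
#'
#' Forward model for channel c:
#' \code{oxyHb_c(t) = betaTrue[c] * (task boxcar x HRF)(t) + correlated AR(1)
#' noise + physiological sinusoids + drift}; the surrogate deoxyHb is
#' \code{-deoxyGamma * oxyHb} plus small independent noise. Intensities are
#' produced by the exact inverse of the MBLL conversion, with motion spikes
#' added in the optical-density domain.
#'
#' @param montage A \linkS4class{Montage}.
#' @param design A \linkS4class{BlockDesign}.
#' @param spec An \linkS4class{EffectSpec}.
#' @param hrf An \linkS4class{HrfParams} (default canonical).
#' @param optics An \linkS4class{OpticsParams}.
#' @param seed integer seed; mandatory (reproducibility is part of the
#'   contract).
#' @return list with elements \code{truth} (noise-and-all
#'   \linkS4class{HemoTimeSeries} before the optical domain), \code{raw}
#'   (\linkS4class{RawIntensity}), \code{betaTrue}, \code{regressor} (the
#'   convolved task boxcar) and \code{seed}.
#' @export
simulateSubject <- function(montage, design, spec = effectSpec(montage),
                            hrf = hrfParams(),
                            optics = suppressMessages(opticsParams()),
                            seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  set.seed(seed)
  n <- nSamples(design)
  n_ch <- nChannels(montage)
  fs <- design@samplingRate
  t_sec <- (seq_len(n) - 1) / fs

  kernel <- canonicalHrf(fs, hrf)
  reg <- conv_causal(taskIndicator(design), kernel)
  oxy <- outer(reg, spec@betaTrue)

  if (spec@innovationSd > 0) {
    R <- latentCovariance(spec, n_ch)
    innov <- matrix(rnorm(n * n_ch), n, n_ch) %*% chol(R) * spec@innovationSd
    noise <- apply(innov, 2, function(e)
      as.numeric(stats::filter(e, spec@ar, method = "recursive")))
    oxy <- oxy + noise
  }
  if (nrow(spec@physio) > 0) {
    for (i in seq_len(nrow(spec@physio))) {
      phase <- runif(n_ch, 0, 2 * pi)
      oxy <- oxy + spec@physio$amplitude[i] *
        sin(outer(2 * pi * spec@physio$freq[i] * t_sec, phase, "+"))
    }
  }
  oxy <- oxy + spec@driftSlope * t_sec

  deoxy <- -spec@deoxyGamma * oxy
  if (spec@deoxyNoiseSd > 0)
    deoxy <- deoxy + matrix(rnorm(n * n_ch, sd = spec@deoxyNoiseSd), n, n_ch)

  truth <- new("HemoTimeSeries", samplingRate = fs, oxy = oxy, deoxy = deoxy)

  sep <- channelTable(montage)$separation
  od <- odFromHemoglobin(truth, optics, separations = sep)
  if (spec@spikeRate > 0 && spec@spikeMagnitude > 0) {
    minutes <- totalDuration(design) / 60
    for (c in seq_len(n_ch)) {
      n_spk <- rpois(1, spec@spikeRate * minutes)
      if (n_spk > 0) {
        pos <- sample.int(n, n_spk)
        amp <- spec@spikeMagnitude * sample(c(-1, 1), n_spk, replace = TRUE)
        od[pos, c, 1] <- od[pos, c, 1] + amp
        od[pos, c, 2] <- od[pos, c, 2] + amp
      }
    }
  }
  baseline <- matrix(1, n_ch, 2)
  raw <- intensityFromOD(od, baseline, fs, optics@wavelengths)
  list(truth = truth, raw = raw, betaTrue = spec@betaTrue, regressor = reg,
       seed = seed)
}

#' Simulate a longitudinal cohort
#'
#' Simulates \code{nSubjects} subjects over the given sessions. Per-subject
#' seeds are derived deterministically from the master seed. Each subject's
#' activation is placed on a single active channel drawn from
#' \code{activeChannels} (recycled over subjects) unless the effect spec
#' already carries a nonzero \code{betaTrue}. Session-specific overrides
#' (named lists of \linkS4class{EffectSpec} fields) allow e.g. raising the
#' left-hemisphere within-module correlation at a later session to emulate a
#' treatment-induced network change.
#'
#' @param nSubjects number of subjects (>= 1).
#' @param sessions character vector of session labels.
#' @param montage,design,spec,hrf,optics simulation inputs; see
#'   [simulateSubject()].
#' @param overrides named list: session label -> list of spec field
#'   replacements. Unknown session labels are an error.
#' @param activeChannels one active channel per subject (recycled); the
#'   default follows the stimulation-site channels of the motivating cohort
#'   (5, 8, 10, 10, 11).
#' @param activeAmplitude activation amplitude placed on the active channel
#'   (mol/L per regressor unit).
#' @param seed master integer seed.
#' @return An object of class \code{"nirsCohort"}: a list with
#'   \code{montage}, \code{design}, \code{sessions}, \code{subjects},
#'   \code{activeChannels} and \code{recordings[[subject]][[session]]}, each
#'   recording as returned by [simulateSubject()].
#' @export
simulateCohort <- function(nSubjects = 5, sessions = c("T0", "T1", "T2"),
                           montage = defaultMontage(),
                           design = makeBlockDesign(),
                           spec = effectSpec(montage),
                           overrides = list(),
                           activeChannels = c(5, 8, 10, 10, 11),
                           activeAmplitude = 5e-8,
                           hrf = hrfParams(),
                           optics = suppressMessages(opticsParams()),
                           seed) {
  if (nSubjects < 1) stop("need at least one subject")
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  bad <- setdiff(names(overrides), sessions)
  if (length(bad)) stop("unknown session label(s) in overrides: ",
                        paste(bad, collapse = ", "))
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1,
                             nSubjects * length(sessions)),
                  nSubjects, length(sessions),
                  dimnames = list(NULL, sessions))
  active <- rep_len(activeChannels, nSubjects)
  subjects <- sprintf("S%02d", seq_len(nSubjects))
  recordings <- vector("list", nSubjects)
  names(recordings) <- subjects
  for (s in seq_len(nSubjects)) {
    subj_spec <- spec
    if (all(spec@betaTrue == 0)) {
      beta <- rep(0, nChannels(montage))
      beta[active[s]] <- activeAmplitude
      subj_spec <- modifyEffectSpec(spec, betaTrue = beta)
    }
    recordings[[s]] <- vector("list", length(sessions))
    names(recordings[[s]]) <- sessions
    for (j in seq_along(sessions)) {
      ses_spec <- subj_spec
      ov <- overrides[[sessions[j]]]
      if (!is.null(ov)) ses_spec <- do.call(modifyEffectSpec, c(list(ses_spec), ov))
      recordings[[s]][[j]] <- simulateSubject(
        montage, design, ses_spec, hrf = hrf, optics = optics,
        seed = seeds[s, j])
    }
  }
  structure(list(montage = montage, design = design, sessions = sessions,
                 subjects = subjects, activeChannels = active,
                 recordings = recordings, seed = seed),
            class = "nirsCohort")
}

#' @export
print.nirsCohort <- function(x, ...) {
  cat(sprintf("nirsCohort: %d subjects x %d sessions (%s), %d channels, %gs @ %g Hz\n",
              length(x$subjects), length(x$sessions),
              paste(x$sessions, collapse = ","), nChannels(x$montage),
              totalDuration(x$design), samplingRate(x$design)))
  invisible(x)
}
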