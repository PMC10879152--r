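#' Probe geometry presets
#'
#' "spinal" is a 32-channel linear shaft (100 um spacing, recorded at
#' 25 kHz); "drg" is a 32-channel array (recorded at 30 kHz).  The grid pitch
#' of the array preset is nominal; current-source-density analysis is
#' restricted to linear probes.
#'
#' @param preset "spinal" or "drg"; ignored when \code{layout} is given.
#' @param nChannels number of channels.
#' @param layout "linear" or "grid" for a custom geometry.
#' @param spacingUm inter-channel spacing (um).
#' @return a \linkS4class{ProbeGeometry}.
#' @export
probeGeometry <- function(preset = c("spinal", "drg"), nChannels = 32,
                          layout = NULL, spacingUm = 100) {
  if (is.null(layout)) {
    preset <- match.arg(preset)
    layout <- if (preset == "spinal") "linear" else "grid"
  }
  new("ProbeGeometry", nChannels = as.integer(nChannels), layout = layout,
      spacingUm = spacingUm)
}

#' Default sampling rate of a preset
#'
#' @param preset "spinal" (25 kHz) or "drg" (30 kHz).
#' @return sampling frequency in Hz.
#' @export
presetSamplingRate <- function(preset = c("spinal", "drg")) {
  switch(match.arg(preset), spinal = 25000, drg = 30000)
}

#' Noise model constructor for synthetic recordings
#'
#' @param backgroundSd Gaussian background SD (uV).
#' @param backgroundCornerHz corner of the one-pole low-pass shaping the
#'   background spectrum (red noise); \code{Inf} for white.
#' @param lineAmplitudeUv powerline amplitude per harmonic (uV; 50, 100,
#'   ... Hz).
#' @param driftAmplitudeUv slow drift amplitude (uV).
#' @param driftFreqHz drift frequency (Hz).
#' @param artifactRate rate of large transient artifacts (events/s).
#' @param artifactAmplitudeSd artifact amplitude in background-SD multiples.
#' @param artifactWidthMs artifact width (ms).
#' @return a \linkS4class{NoiseConfig}.
#' @export
noiseConfig <- function(backgroundSd = 8, backgroundCornerHz = 300,
                        lineAmplitudeUv = c(15, 6, 3),
                        driftAmplitudeUv = 40, driftFreqHz = 0.4,
                        artifactRate = 0.02, artifactAmplitudeSd = 20,
                        artifactWidthMs = 4) {
  new("NoiseConfig", backgroundSd = backgroundSd,
      backgroundCornerHz = backgroundCornerHz,
      lineAmplitudeUv = lineAmplitudeUv, driftAmplitudeUv = driftAmplitudeUv,
      driftFreqHz = driftFreqHz, artifactRate = artifactRate,
      artifactAmplitudeSd = artifactAmplitudeSd,
      artifactWidthMs = artifactWidthMs)
}

#' Natural-touch drive profile
#'
#' Aggregate afferent-population firing rate evoked by a single touch
#' contact: a sharp onset burst (fast-adapting units at the indentation),
#' an adapting sustained plateau (slowly adapting units) and a smaller
#' offset burst at release.  The default span of 0.8 s matches the duration
#' of the natural-touch response analysed downstream.  \code{"bump"} gives a
#' smooth unimodal raised-cosine profile instead.
#'
#' @param duration profile span (s).
#' @param profileShape "ramp_hold" (default) or "bump".
#' @param peakRate peak aggregate rate (spikes/s), must be positive.
#' @param timeStep sample interval (s).
#' @param seed seed for the small multiplicative amplitude jitter.
#' @return a \linkS4class{RateProfile}.
#' @export
makeTouchDrive <- function(duration = 0.8,
                           profileShape = c("ramp_hold", "bump"),
                           peakRate = 150, timeStep = 0.001, seed = 1,
                           nUnits = 120) {
  profileShape <- match.arg(profileShape)
  stopifnot(peakRate > 0, duration > 0)
  n <- round(duration / timeStep)
  if (profileShape == "ramp_hold") {
    # expected aggregate response of a mixed afferent population to repeated
    # light contacts (rubbing): the standard ramp-and-hold duty cycle, time
    # compressed to fit the touch-response span
    scale <- duration / 2
    stim <- makeRampAndHold(duration = duration, onPhase = 0.15 * scale,
                            offPhase = 0.3 * scale, amplitude = 1,
                            noiseFraction = 0.005, timeStep = timeStep,
                            seed = seed)
    pop <- buildPopulation("FULL", nUnits, seed = seed)
    r <- colMeans(afferentRates(pop, stim))
    r <- peakRate * r / max(r)
    r <- r[seq_len(n)]
  } else {
    t <- (seq_len(n) - 0.5) * timeStep
    jit <- withSeed(seed, runif(1, 0.95, 1.05))
    r <- jit * peakRate * (1 - cos(2 * pi * t / duration)) / 2
  }
  new("RateProfile", binEdges = seq(0, by = timeStep, length.out = n + 1L),
      rate = r, nTrials = 1L, binWidthMethod = "fixed", smoothing = list())
}

# Biphasic extracellular spike waveform template at sampling rate fs,
# normalized so its most negative point is -1.
spikeTemplate <- function(fs) {
  t <- seq(0, 0.0012, by = 1 / fs)
  w <- -exp(-((t - 3e-4) / 1e-4)^2) + 0.45 * exp(-((t - 7e-4) / 2e-4)^2)
  w / abs(min(w))
}

# Add scaled template occurrences to a voltage trace in place (returns the
# modified trace).  Duplicate sample indices are accumulated correctly.
addSpikes <- function(x, idx, amps, template) {
  if (!length(idx)) return(x)
  agg <- rowsum(amps, idx)
  uidx <- as.integer(rownames(agg))
  L <- length(template)
  n <- length(x)
  for (k in seq_len(L)) {
    pos <- uidx + k - 1L
    ok <- pos >= 1L & pos <= n
    x[pos[ok]] <- x[pos[ok]] + agg[ok, 1] * template[k]
  }
  x
}

#' Synthesize a ground-truthed multichannel extracellular recording
#'
#' Emulates the recordings of the animal experiments.  The drive is either a
#' \linkS4class{StimTrain} (electrical: every pulse recruits each channel's
#' multi-unit activity with probability \code{pRecruit} at a short jittered
#' latency, synchronizing channels) or a \linkS4class{RateProfile} (natural
#' touch: channels fire as independent inhomogeneous Poisson processes
#' scaled by per-channel gains).  Trials are concatenated back to back; the
#' voltage of each channel is the sum of
#' \itemize{
#' \item spike waveform templates at the true spike times (default 6 background
#'   SDs at the negative peak),
#' \item an LFP component: two temporal components (a fast envelope of the
#'   drive intensity and a slower, delayed one) riding on trial-locked
#'   oscillatory carriers in the LFP band, weighted along the probe by two
#'   gaussian current-source depth profiles shared between drive types;
#'   electrical drives are strong and dominated by the fast component
#'   (synchronized volleys), natural drives are weaker with a stronger slow
#'   component,
#' \item 50 Hz line noise and harmonics, slow drift, Gaussian background and
#'   occasional large common-mode artifacts per \code{\link{noiseConfig}}.
#' }
#'
#' @param drive a \linkS4class{StimTrain}, a \linkS4class{RateProfile}, or
#'   NULL for a drive-free recording.
#' @param geometry a \linkS4class{ProbeGeometry}.
#' @param noiseCfg a \linkS4class{NoiseConfig}.
#' @param nTrials number of stimulus repetitions.
#' @param trialLength trial window (s); defaults to the drive span.
#' @param samplingRate sampling frequency (Hz).
#' @param seed integer seed.
#' @param pRecruit per-pulse recruitment probability for electrical drives.
#' @param latencyMeanMs,latencyJitterMs response latency mean and SD (ms).
#' @param unitsPerChannel number of fibre groups recruited per channel per
#'   pulse (compound volley); 1 gives one spike per recruiting pulse.
#' @param unitLatencySpacingMs conduction-delay separation between the
#'   fibre groups (ms).
#' @param spikeAmplitudeSd spike peak amplitude in background-SD multiples.
#' @param naturalGain mean spikes-per-second scale applied to a natural
#'   drive profile (per channel, around 1).
#' @param hashRate rate (events/s per channel) of low-amplitude background
#'   multi-unit hash -- distant units too small to isolate, which inflate
#'   the robust noise estimate exactly as in real extracellular recordings;
#'   not part of the ground truth.
#' @param hashAmplitudeSd hash peak amplitude in background-SD multiples.
#' @param lfpGainUv,lfpKappa LFP forward-model gain (uV) and slow-component
#'   mixing weight; the defaults depend on the drive type (strong and
#'   fast-component-dominated for electrical drives, weaker and mixed for
#'   natural ones), reproducing the along-probe similarity structure of
#'   electrically versus naturally evoked activity.
#' @return list with \code{recording} (\linkS4class{MultichannelRecording})
#'   and \code{truth} (\linkS4class{GroundTruth}).
#' @export
synthesizeRecording <- function(drive, geometry = probeGeometry("spinal"),
                                noiseCfg = noiseConfig(), nTrials = 10,
                                trialLength = NULL,
                                samplingRate = 25000, seed = 1,
                                pRecruit = 0.9, latencyMeanMs = 1.5,
                                latencyJitterMs = 0.5, unitsPerChannel = 3,
                                unitLatencySpacingMs = 2.5,
                                spikeAmplitudeSd = 6,
                                naturalGain = 1,
                                hashRate = 150, hashAmplitudeSd = 0.4,
                                lfpGainUv = NULL, lfpKappa = NULL) {
  electrical <- is(drive, "StimTrain")
  natural <- is(drive, "RateProfile")
  if (!electrical && !natural && !is.null(drive))
    stop("unknown drive type: ", class(drive)[1])
  fs <- samplingRate
  span <- if (electrical) drive@duration else if (natural) duration(drive) else 1
  trialLength <- trialLength %||% span
  stopifnot(trialLength > 0, nTrials >= 1)
  nCh <- geometry@nChannels
  nTrialSamp <- round(trialLength * fs)
  N <- nTrialSamp * nTrials
  onsetsS <- (seq_len(nTrials) - 1) * trialLength

  driveLabel <- if (electrical) drive@encoding else if (natural) "NATURAL"
                else "NONE"
  lfpGainUv <- lfpGainUv %||% (if (electrical) 60 else 25)
  lfpKappa <- lfpKappa %||% (if (electrical) 0.25 else 1.2)

  withSeed(seed, {
    ## ---- ground-truth spikes per channel -----------------------------------
    gains <- exp(rnorm(nCh, 0, 0.25))
    spikes <- vector("list", nCh)
    if (electrical) {
      p <- drive@onsets
      jit <- latencyJitterMs / 1000
      # compound volley: each pulse can recruit several fibre groups per
      # channel, at distinct conduction delays
      lats <- (latencyMeanMs + (seq_len(unitsPerChannel) - 1) *
                 unitLatencySpacingMs) / 1000
      for (ch in seq_len(nCh)) {
        st <- unlist(lapply(onsetsS, function(o) {
          unlist(lapply(lats, function(lat) {
            rec <- runif(length(p)) < pRecruit
            tt <- p[rec] + lat + if (jit > 0) rnorm(sum(rec), 0, jit) else 0
            o + tt[tt >= 0 & tt < trialLength]
          }), use.names = FALSE)
        }), use.names = FALSE)
        spikes[[ch]] <- sort(st)
      }
    } else if (natural) {
      dt <- drive@binEdges[2] - drive@binEdges[1]
      for (ch in seq_len(nCh)) {
        st <- unlist(lapply(onsetsS, function(o) {
          o + thinPoisson(naturalGain * gains[ch] * drive@rate, dt,
                          min(duration(drive), trialLength), 0.001)
        }), use.names = FALSE)
        spikes[[ch]] <- sort(st)
      }
    }

    ## ---- LFP component ------------------------------------------------------
    # drive intensity on a 1 ms grid per trial, identical across trials
    lfpDt <- 0.001
    nLfp <- round(trialLength / lfpDt)
    tLfp <- (seq_len(nLfp) - 0.5) * lfpDt
    intensity <- numeric(nLfp)
    if (electrical) {
      intensity <- binCount(drive@onsets,
                            seq(0, trialLength, by = lfpDt)) / lfpDt
    } else if (natural) {
      rp <- approx(x = (drive@binEdges[-1] + head(drive@binEdges, -1)) / 2,
                   y = drive@rate, xout = tLfp, rule = 2)$y
      rp[tLfp > duration(drive)] <- 0
      intensity <- rp
    }
    gauss <- function(x, sdS) {
      half <- ceiling(3 * sdS / lfpDt)
      k <- exp(-((-half:half) * lfpDt)^2 / (2 * sdS^2)); k <- k / sum(k)
      as.numeric(stats::filter(c(rep(0, half), x, rep(0, half)), k,
                               sides = 2))[(half + 1):(half + length(x))]
    }
    e1 <- gauss(intensity, 0.010)
    lagN <- round(0.12 / lfpDt)
    lagged <- c(rep(0, lagN), intensity)[seq_len(nLfp)]
    e2 <- gauss(lagged, 0.08)
    if (max(e1) > 0) e1 <- e1 / max(e1)
    if (max(e2) > 0) e2 <- e2 / max(e2)
    carrier1 <- sin(2 * pi * 85 * tLfp)
    carrier2 <- sin(2 * pi * 45 * tLfp + 1)
    a1trial <- e1 * carrier1
    a2trial <- e2 * carrier2
    # upsample the two temporal components once, then mix per channel
    tFull <- (seq_len(nTrialSamp) - 0.5) / fs
    upsample <- function(a) approx(tLfp, a, xout = tFull, rule = 2)$y
    A1 <- rep(upsample(a1trial), nTrials)
    A2 <- rep(upsample(a2trial), nTrials)
    # gaussian current-source profiles shared between drive types: a dorsal
    # fast source and a deeper slow one; drive types differ only in overall
    # gain and in how strongly the slow component mixes in
    z <- (seq_len(nCh) - 1) * geometry@spacingUm
    span <- max(z) - min(z) + geometry@spacingUm
    z1 <- 0.20 * span
    z2 <- 0.65 * span
    sw1 <- 0.30 * span
    sw2 <- 0.20 * span
    # laminar fine structure: alternating sink/source bands at a few hundred
    # micrometres, fixed by the anatomy and therefore identical across drive
    # types; this is what gives the CSD its spatial structure at the probe
    # pitch
    lamP <- 6 * geometry@spacingUm
    rip1 <- 1 + 0.6 * sin(2 * pi * z / lamP)
    rip2 <- 1 + 0.6 * sin(2 * pi * z / lamP + 2.1)
    w1 <- exp(-(z - z1)^2 / (2 * sw1^2)) * rip1
    w2 <- lfpKappa * exp(-(z - z2)^2 / (2 * sw2^2)) * rip2

    ## ---- noise components ---------------------------------------------------
    tAll <- (seq_len(N) - 0.5) / fs
    line <- numeric(N)
    if (any(noiseCfg@lineAmplitudeUv > 0)) {
      phi <- runif(length(noiseCfg@lineAmplitudeUv), 0, 2 * pi)
      for (h in seq_along(noiseCfg@lineAmplitudeUv))
        if (noiseCfg@lineAmplitudeUv[h] > 0)
          line <- line + noiseCfg@lineAmplitudeUv[h] *
            sin(2 * pi * 50 * h * tAll + phi[h])
    }
    artTimes <- numeric(0)
    artWin <- matrix(numeric(0), ncol = 2)
    artifact <- numeric(N)
    if (noiseCfg@artifactRate > 0 && noiseCfg@artifactAmplitudeSd > 0) {
      nArt <- rpois(1, noiseCfg@artifactRate * N / fs)
      if (nArt > 0) {
        artTimes <- sort(runif(nArt, 0.05, N / fs - 0.05))
        wS <- noiseCfg@artifactWidthMs / 1000
        for (ta in artTimes) {
          i0 <- max(1L, round((ta - 3 * wS) * fs))
          i1 <- min(N, round((ta + 3 * wS) * fs))
          seg <- (i0:i1) / fs
          artifact[i0:i1] <- artifact[i0:i1] +
            noiseCfg@artifactAmplitudeSd * noiseCfg@backgroundSd *
            exp(-(seg - ta)^2 / (2 * (wS / 2)^2))
        }
        artWin <- cbind(artTimes - 3 * wS, artTimes + 3 * wS)
      }
    }

    ## ---- assemble channels --------------------------------------------------
    template <- spikeTemplate(fs)
    v <- matrix(0, nCh, N)
    phiDrift <- runif(nCh, 0, 2 * pi)
    corner <- noiseCfg@backgroundCornerHz
    aPole <- if (is.finite(corner)) exp(-2 * pi * corner / fs) else 0
    for (ch in seq_len(nCh)) {
      x <- if (noiseCfg@backgroundSd > 0) {
        w <- rnorm(N)
        if (aPole > 0) {
          # two cascaded one-pole sections: ~f^-4 spectral roll-off, the
          # steep red spectrum of extracellular background noise
          w <- as.numeric(stats::filter(w, aPole, method = "recursive"))
          w <- as.numeric(stats::filter(w, aPole, method = "recursive"))
          w <- w / sd(w)
        }
        noiseCfg@backgroundSd * w
      } else numeric(N)
      x <- x + lfpGainUv * (w1[ch] * A1 + w2[ch] * A2)
      if (noiseCfg@driftAmplitudeUv > 0)
        x <- x + noiseCfg@driftAmplitudeUv *
          sin(2 * pi * noiseCfg@driftFreqHz * tAll + phiDrift[ch])
      x <- x + line + artifact
      st <- spikes[[ch]]
      if (length(st)) {
        # template's negative peak is -1, so this is the (positive) peak size
        amp <- spikeAmplitudeSd * noiseCfg@backgroundSd *
          exp(rnorm(length(st), 0, 0.1))
        idx <- pmax(1L, pmin(N, round(st * fs) + 1L))
        x <- addSpikes(x, idx, amp, template)
      }
      if (hashRate > 0 && hashAmplitudeSd > 0) {
        nh <- rpois(1, hashRate * N / fs)
        if (nh > 0) {
          ht <- runif(nh, 0, N / fs)
          hAmp <- hashAmplitudeSd * noiseCfg@backgroundSd *
            exp(rnorm(nh, 0, 0.15))
          x <- addSpikes(x, pmax(1L, pmin(N, round(ht * fs) + 1L)),
                         hAmp, template)
        }
      }
      v[ch, ] <- x
    }
    rec <- new("MultichannelRecording", samplingRate = fs, voltages = v,
               geometry = geometry, trialEvents = onsetsS)
    truth <- new("GroundTruth", spikes = spikes, artifactWindows = artWin,
                 rateProfile = if (natural) drive else NULL,
                 driveLabel = driveLabel)
    list(recording = rec, truth = truth)
  })
}

#' Embed additional large artifacts into a recording
#'
#' Adds gaussian-shaped transients of the stated amplitude (in multiples of
#' each channel's robust background SD) at the given times, common to all
#' channels, and records the affected windows in the ground truth.
#'
#' @param recording a \linkS4class{MultichannelRecording}.
#' @param truth the paired \linkS4class{GroundTruth}.
#' @param times artifact centre times (s), within the recording span.
#' @param amplitudeSdMultiple artifact amplitude in background-SD multiples.
#' @param widthMs artifact width (ms).
#' @return list with the modified \code{recording} and updated \code{truth}.
#' @export
embedArtifacts <- function(recording, truth, times, amplitudeSdMultiple = 20,
                           widthMs = 4) {
  if (!length(times))
    return(list(recording = recording, truth = truth))
  fs <- recording@samplingRate
  N <- ncol(recording@voltages)
  if (any(times < 0 | times > N / fs)) stop("artifact time out of range")
  wS <- widthMs / 1000
  v <- recording@voltages
  sig <- channelSigmas(v)
  for (ta in times) {
    i0 <- max(1L, round((ta - 3 * wS) * fs))
    i1 <- min(N, round((ta + 3 * wS) * fs))
    seg <- (i0:i1) / fs
    bump <- exp(-(seg - ta)^2 / (2 * (wS / 2)^2))
    v[, i0:i1] <- v[, i0:i1] +
      (amplitudeSdMultiple * sig) %o% bump
  }
  recording@voltages <- v
  truth@artifactWindows <- rbind(truth@artifactWindows,
                                 cbind(times - 3 * wS, times + 3 * wS))
  list(recording = recording, truth = truth)
}

#' Cross-channel spike-time synchrony index
#'
#' Fraction of spikes that have a spike on at least one other channel within
#' \code{tol} seconds.  Electrically driven recordings, where each pulse
#' recruits most channels at nearly identical latency, score close to 1;
#' independent natural-drive spiking scores much lower.
#'
#' @param spikes list of per-channel spike-time vectors.
#' @param tol coincidence tolerance (s), default 1 ms.
#' @return a scalar in \code{[0, 1]}.
#' @export
crossChannelSynchrony <- function(spikes, tol = 0.001) {
  nCh <- length(spikes)
  if (nCh < 2) return(0)
  total <- 0L
  sync <- 0L
  for (ch in seq_len(nCh)) {
    st <- spikes[[ch]]
    if (!length(st)) next
    others <- sort(unlist(spikes[-ch], use.names = FALSE))
    total <- total + length(st)
    if (!length(others)) next
    pos <- findInterval(st, others)
    dLeft <- ifelse(pos >= 1, st - others[pmax(pos, 1L)], Inf)
    dRight <- ifelse(pos < length(others),
                     others[pmin(pos + 1L, length(others))] - st, Inf)
    sync <- sync + sum(pmin(dLeft, dRight) <= tol)
  }
  if (total == 0L) 0 else sync / total
}
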