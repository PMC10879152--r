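#' Smooth a rate profile
#'
#' Convolves the binned rates with a gaussian or moving-average kernel on the
#' same bin grid.  Kernel weights are renormalized at the edges so that the
#' total rate mass is conserved (within 1% for interior bins) and
#' non-negativity is preserved.
#'
#' @param profile a \linkS4class{RateProfile}.
#' @param kernel "gaussian" (width = standard deviation) or
#'   "moving_average" (width = window length).
#' @param widthS kernel width in seconds; must cover at least one bin.
#' @return a smoothed \linkS4class{RateProfile} on the same grid.
#' @export
smoothProfile <- function(profile, kernel = c("gaussian", "moving_average"),
                          widthS) {
  kernel <- match.arg(kernel)
  stopifnot(widthS > 0)
  bw <- profile@binEdges[2] - profile@binEdges[1]
  if (widthS < bw) stop("smoothing width is smaller than one bin")
  r <- profile@rate
  n <- length(r)
  if (kernel == "gaussian") {
    half <- max(1L, ceiling(3 * widthS / bw))
    k <- exp(-((-half:half) * bw)^2 / (2 * widthS^2))
  } else {
    half <- max(1L, floor(widthS / bw / 2))
    k <- rep(1, 2L * half + 1L)
  }
  k <- k / sum(k)
  smoothed <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    w <- k[(lo - i + half + 1L):(hi - i + half + 1L)]
    sum(r[lo:hi] * w) / sum(w)
  }, numeric(1))
  new("RateProfile", binEdges = profile@binEdges, rate = smoothed,
      nTrials = profile@nTrials, binWidthMethod = profile@binWidthMethod,
      smoothing = list(kernel = kernel, width = widthS))
}

#' Map a rate profile onto a stimulation frequency profile
#'
#' Affine map of the (smoothed) PSTH onto \code{[fMin, fMax]}: zero rate maps
#' to \code{fMin} and the profile maximum to \code{fMax}, so the stimulation
#' frequency follows the population firing rate while the amplitude stays
#' constant.
#'
#' @param profile a \linkS4class{RateProfile} with a positive maximum.
#' @param fMin,fMax frequency bounds in Hz (\code{fMax > fMin >= 0}).
#' @return a \linkS4class{FrequencyProfile} sampled on the profile bins.
#' @export
profileToFrequency <- function(profile, fMin = 0, fMax = 100) {
  if (!(fMax > fMin) || fMin < 0) stop("need fMax > fMin >= 0")
  r <- profile@rate
  m <- max(r)
  if (m <= 0) stop("all-zero profile: no scale for the frequency map")
  freq <- fMin + (fMax - fMin) * r / m
  new("FrequencyProfile", timeStep = profile@binEdges[2] - profile@binEdges[1],
      freq = freq, fMin = fMin, fMax = fMax)
}

#' Place stimulation pulses by time-rescaling a frequency profile
#'
#' Emits the first pulse at the first instant with positive frequency (t = 0
#' for a profile that starts active) and a further pulse whenever the running
#' integral of the instantaneous frequency crosses the next whole number
#' (the frequency profile is treated as piecewise constant per sample).
#' Pulses lie in \code{[0, duration)}; a constant profile therefore reduces
#' to the regular train of \code{\link{makeTonic}} and the pulse count equals
#' \code{ceiling(integral of f dt)}.
#'
#' @param freqProfile a \linkS4class{FrequencyProfile}.
#' @param duration train duration (s); must not exceed the profile span.
#' @param amplitudeUa constant pulse amplitude (uA).
#' @param pulseWidthUs constant pulse width (us).
#' @param encoding encoding label stored on the train.
#' @return a \linkS4class{StimTrain}.
#' @export
frequencyToPulseTimes <- function(freqProfile, duration,
                                  amplitudeUa = 60, pulseWidthUs = 500,
                                  encoding = "BIOM_FULL") {
  f <- freqProfile@freq
  dt <- freqProfile@timeStep
  if (any(f < 0)) stop("negative frequency sample")
  span <- length(f) * dt
  if (duration > span + 1e-9) stop("duration exceeds the profile span")
  nSteps <- min(length(f), ceiling(duration / dt))
  f <- f[seq_len(nSteps)]
  cum <- c(0, cumsum(f * dt))     # integral at sample boundaries
  total <- cum[nSteps + 1]
  times <- numeric(0)
  if (total > 0) {
    hi <- cum[-1]
    # pulse k is placed where the running integral strictly exceeds k, by
    # inverting the piecewise-linear integral within that sample
    times <- vapply(seq(0, ceiling(total)), function(k) {
      i <- which(hi > k + 1e-9 & f > 0)[1]
      if (is.na(i)) return(NA_real_)
      (i - 1) * dt + max(k - cum[i], 0) / f[i]
    }, numeric(1))
    times <- times[!is.na(times) & times < duration - 1e-12]
  }
  n <- length(times)
  new("StimTrain", onsets = times, amplitudeUa = rep(amplitudeUa, n),
      pulseWidthUs = rep(pulseWidthUs, n), encoding = encoding,
      duration = duration)
}

#' Tonic (constant-frequency) stimulation train
#'
#' The conventional neuroprosthetic encoding: a regular pulse train at
#' \code{freq} Hz, first pulse at t = 0.
#'
#' @param freq stimulation frequency (Hz), default 50.
#' @param duration train duration (s); pulses lie in \code{[0, duration)}.
#' @param amplitudeUa,pulseWidthUs constant pulse parameters.
#' @return a \linkS4class{StimTrain} labelled TONIC.
#' @export
makeTonic <- function(freq = 50, duration, amplitudeUa = 60,
                      pulseWidthUs = 500) {
  stopifnot(freq > 0, duration > 0)
  n <- ceiling(freq * duration - 1e-9)
  times <- (seq_len(n) - 1) / freq
  times <- times[times < duration - 1e-12]
  n <- length(times)
  new("StimTrain", onsets = times, amplitudeUa = rep(amplitudeUa, n),
      pulseWidthUs = rep(pulseWidthUs, n), encoding = "TONIC",
      duration = duration)
}

#' Poisson stimulation train
#'
#' Pulse intervals are i.i.d. exponential, truncated at the train duration,
#' so intervals are uncorrelated.  Intervals below the refractory floor
#' (which protects the biphasic pulse shape) are redrawn, and the
#' exponential rate is set so that the mean interval including the floor is
#' exactly \code{1/meanFreq}.
#'
#' @param meanFreq mean pulse rate (Hz), default 50.
#' @param duration train duration (s).
#' @param amplitudeUa,pulseWidthUs constant pulse parameters.
#' @param seed integer seed.
#' @param refractory minimum inter-pulse interval (s); defaults to 2.2 times
#'   the biphasic-phase width.
#' @return a \linkS4class{StimTrain} labelled POISSON.
#' @export
makePoisson <- function(meanFreq = 50, duration, amplitudeUa = 60,
                        pulseWidthUs = 500, seed = 1,
                        refractory = 2.2 * pulseWidthUs * 1e-6) {
  stopifnot(meanFreq > 0, duration > 0, refractory < 1 / meanFreq)
  # redrawing below the floor leaves gap ~ refractory + Exp(rate), so this
  # rate keeps the mean interval at exactly 1/meanFreq
  rate <- 1 / (1 / meanFreq - refractory)
  times <- withSeed(seed, {
    t <- 0
    out <- numeric(0)
    repeat {
      gap <- rexp(1, rate)
      if (gap < refractory) next
      t <- t + gap
      if (t >= duration) break
      out <- c(out, t)
    }
    out
  })
  n <- length(times)
  new("StimTrain", onsets = times, amplitudeUa = rep(amplitudeUa, n),
      pulseWidthUs = rep(pulseWidthUs, n), encoding = "POISSON",
      duration = duration)
}

#' Linear amplitude neuromodulation from a pressure trace
#'
#' Regular 50 Hz train whose injected charge follows the normalized pressure
#' linearly between the perceptual threshold charge \code{qMinNc} and the
#' maximum comfortable charge \code{qMaxNc}; the charge is realized through
#' the pulse amplitude at fixed pulse width.  Epochs at or below
#' \code{pressureThreshold} emit no pulses (below the perceptual threshold).
#'
#' @param pressure numeric pressure trace normalized to \code{[0, 1]}.
#' @param timeStep sample interval of \code{pressure} (s).
#' @param qMinNc,qMaxNc charge bounds (nC), \code{qMinNc < qMaxNc}.
#' @param freq pulse rate (Hz), default 50.
#' @param pulseWidthUs fixed pulse width (us).
#' @param pressureThreshold pressures at or below this value are silent.
#' @return a \linkS4class{StimTrain} labelled LIN.
#' @export
makeLinear <- function(pressure, timeStep, qMinNc, qMaxNc, freq = 50,
                       pulseWidthUs = 500, pressureThreshold = 0) {
  if (any(pressure < 0 | pressure > 1)) stop("pressure must lie in [0, 1]")
  stopifnot(qMinNc < qMaxNc)
  dur <- length(pressure) * timeStep
  grid <- makeTonic(freq, dur)@onsets
  idx <- pmin(floor(grid / timeStep) + 1L, length(pressure))
  p <- pressure[idx]
  keep <- p > pressureThreshold
  grid <- grid[keep]
  charge <- qMinNc + p[keep] * (qMaxNc - qMinNc)
  amplitude <- charge * 1000 / pulseWidthUs
  new("StimTrain", onsets = grid, amplitudeUa = amplitude,
      pulseWidthUs = rep(pulseWidthUs, length(grid)), encoding = "LIN",
      duration = dur)
}

#' Time-discrete neuromodulation from contact events
#'
#' Delivers a short tonic burst (default 0.5 s at 50 Hz) at each press or
#' release event; bursts that overlap are merged into a single burst without
#' duplicate pulses.
#'
#' @param events data.frame with columns \code{time} (s, sorted) and
#'   \code{type} ("press" or "release").
#' @param burstDuration burst length per event (s).
#' @param freq pulse rate within a burst (Hz).
#' @param amplitudeUa,pulseWidthUs constant pulse parameters.
#' @param duration total train duration (s); defaults to the end of the last
#'   burst.
#' @return a \linkS4class{StimTrain} labelled DISC.
#' @export
makeDiscrete <- function(events, burstDuration = 0.5, freq = 50,
                         amplitudeUa = 60, pulseWidthUs = 500,
                         duration = NULL) {
  stopifnot(is.data.frame(events), all(c("time", "type") %in% names(events)))
  if (!all(events$type %in% c("press", "release")))
    stop("event types must be 'press' or 'release'")
  if (is.unsorted(events$time)) stop("events must be sorted in time")
  starts <- events$time
  ends <- starts + burstDuration
  # merge overlapping bursts
  merged <- list()
  if (length(starts)) {
    curS <- starts[1]; curE <- ends[1]
    for (i in seq_along(starts)[-1]) {
      if (starts[i] <= curE) curE <- max(curE, ends[i])
      else { merged[[length(merged) + 1L]] <- c(curS, curE); curS <- starts[i]; curE <- ends[i] }
    }
    merged[[length(merged) + 1L]] <- c(curS, curE)
  }
  times <- unlist(lapply(merged, function(iv) {
    k <- seq(iv[1], iv[2] - 1e-12, by = 1 / freq)
    k[k < iv[2] - 1e-12]
  }), use.names = FALSE) %||% numeric(0)
  dur <- duration %||% (if (length(merged)) max(vapply(merged, `[`, numeric(1), 2)) else 0)
  n <- length(times)
  new("StimTrain", onsets = times, amplitudeUa = rep(amplitudeUa, n),
      pulseWidthUs = rep(pulseWidthUs, n), encoding = "DISC", duration = dur)
}

#' Sinusoidal pulse-width neuromodulation
#'
#' Regular train at \code{freq} Hz with constant amplitude whose pulse width
#' oscillates sinusoidally between \code{pwMinUs} and \code{pwMaxUs} at
#' \code{modulationFreq} Hz (mid-width at t = 0, maximum at the first
#' quarter period).
#'
#' @param freq pulse rate (Hz).
#' @param duration train duration (s).
#' @param amplitudeUa constant amplitude (uA).
#' @param pwMinUs,pwMaxUs pulse-width bounds (us), \code{pwMinUs <= pwMaxUs}.
#' @param modulationFreq modulation frequency (Hz), must be positive.
#' @return a \linkS4class{StimTrain} labelled SINUS_PW.
#' @export
makeSinusoidalPw <- function(freq = 50, duration, amplitudeUa = 60,
                             pwMinUs = 100, pwMaxUs = 500,
                             modulationFreq = 1) {
  if (modulationFreq <= 0) stop("modulationFreq must be positive")
  if (pwMinUs > pwMaxUs) stop("need pwMinUs <= pwMaxUs")
  base <- makeTonic(freq, duration, amplitudeUa, 0)
  t <- base@onsets
  mid <- (pwMinUs + pwMaxUs) / 2
  amp <- (pwMaxUs - pwMinUs) / 2
  pw <- mid + amp * sin(2 * pi * modulationFreq * t)
  new("StimTrain", onsets = t, amplitudeUa = rep(amplitudeUa, length(t)),
      pulseWidthUs = pw, encoding = "SINUS_PW", duration = duration)
}

#' Validate a train against the charge safety limit
#'
#' Flags every pulse whose per-pulse charge (amplitude x width) exceeds the
#' chemical safety limit of the implanted electrode (default 120 nC).
#'
#' @param train a \linkS4class{StimTrain}.
#' @param limitNc charge limit per pulse in nC.
#' @return a \linkS4class{ChargeSafetyReport}.
#' @examples
#' tr <- makeTonic(50, 2, amplitudeUa = 60, pulseWidthUs = 500)
#' validateCharge(tr)   # 30 nC per pulse: pass
#' @export
validateCharge <- function(train, limitNc = 120) {
  q <- chargePerPulse(train)
  viol <- which(q > limitNc)
  new("ChargeSafetyReport", limitNc = limitNc, violations = as.integer(viol),
      pass = length(viol) == 0L)
}

#' Design a biomimetic stimulation train from a simulated population
#'
#' Runs the full design chain: ramp-and-hold stimulus, afferent population
#' simulation, population PSTH, smoothing, affine mapping onto a stimulation
#' frequency range and time-rescaled pulse placement with constant amplitude.
#'
#' @param composition afferent composition ("FULL" or one class).
#' @param nUnits population size (total for FULL).
#' @param stimulus optional \linkS4class{PressureStimulus}; defaults to the
#'   standard 2 s ramp-and-hold.
#' @param binWidth PSTH bin width (s).
#' @param smoothWidth gaussian smoothing width (s).
#' @param fMin,fMax stimulation frequency bounds (Hz).
#' @param amplitudeUa,pulseWidthUs constant pulse parameters.
#' @param seed integer seed for population and simulation.
#' @return list with the \code{train} (\linkS4class{StimTrain}),
#'   \code{freqProfile}, smoothed \code{psth} and the \code{stimulus}.
#' @export
designBiomimeticTrain <- function(composition = "FULL", nUnits = 160,
                                  stimulus = NULL, binWidth = 0.01,
                                  smoothWidth = 0.03, fMin = 0, fMax = 100,
                                  amplitudeUa = 60, pulseWidthUs = 500,
                                  seed = 1) {
  stimulus <- stimulus %||% makeRampAndHold(seed = seed)
  pop <- buildPopulation(composition, nUnits, seed = seed)
  resp <- simulateResponses(pop, stimulus, seed = seed + 1L)
  psth <- populationPsth(resp, binWidth)
  sm <- smoothProfile(psth, "gaussian", smoothWidth)
  fp <- profileToFrequency(sm, fMin, fMax)
  lab <- paste0("BIOM_", composition)
  train <- frequencyToPulseTimes(fp, duration(stimulus), amplitudeUa,
                                 pulseWidthUs, encoding = lab)
  list(train = train, freqProfile = fp, psth = sm, stimulus = stimulus)
}
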