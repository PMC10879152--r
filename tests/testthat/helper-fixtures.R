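# Shared fixtures for the test suite.  Everything is generated in code; the
# sizes are kept small so individual files run in seconds.

# A single-unit population with fixed (non-random) parameters, for
# deterministic rate-model checks.
fixedUnitPopulation <- function(class, gainStatic = 60, gainDynamic = 8,
                                gainAccel = 0.12, tauAdapt = 0.6,
                                saturation = 300, spontaneous = 0) {
  units <- data.frame(class = class, x = 50, y = 100,
                      gainStatic = gainStatic, gainDynamic = gainDynamic,
                      gainAccel = gainAccel, tauAdapt = tauAdapt,
                      saturation = saturation, spontaneous = spontaneous)
  new("AfferentPopulation", units = units,
      composition = if (length(unique(class)) == 1L) class[1] else "FULL",
      seed = 0L)
}

# Constant-frequency profile (for pulse-placement checks).
constantFrequencyProfile <- function(freq, duration, timeStep = 0.01) {
  n <- round(duration / timeStep)
  new("FrequencyProfile", timeStep = timeStep, freq = rep(freq, n),
      fMin = 0, fMax = freq)
}

# Small synthetic spinal-style recording driven by a tonic train; returns the
# synthesizeRecording() list.  Kept short to bound test time.
smallTonicRecording <- function(seed, nTrials = 2, trialLength = 1.5,
                                fs = 25000, ...) {
  synthesizeRecording(makeTonic(50, trialLength),
                      geometry = probeGeometry("spinal"),
                      nTrials = nTrials, trialLength = trialLength,
                      samplingRate = fs, seed = seed, ...)
}

# Greedy one-to-one matching of detections to ground truth within a
# tolerance; returns recall and precision pooled over channels.
matchDetections <- function(detected, truth, tol = 0.001) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (ch in seq_along(detected)) {
    d <- detected[[ch]]
    tr <- truth[[ch]]
    used <- logical(length(tr))
    isTP <- logical(length(d))
    for (i in seq_along(d)) {
      j <- which(!used & abs(tr - d[i]) <= tol)
      if (length(j)) {
        used[j[1]] <- TRUE
        isTP[i] <- TRUE
      }
    }
    tp <- tp + sum(isTP)
    fp <- fp + sum(!isTP)
    fn <- fn + sum(!used)
  }
  c(recall = tp / (tp + fn), precision = tp / (tp + fp))
}

# RateProfile from a bare rate vector on a uniform grid.
rateProfileOf <- function(rate, binWidth = 0.01) {
  new("RateProfile",
      binEdges = seq(0, by = binWidth, length.out = length(rate) + 1L),
      rate = rate, nTrials = 1L, binWidthMethod = "fixed",
      smoothing = list())
}
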