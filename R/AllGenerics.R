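#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers: durations,
#' sampling grids, voltages, spike times, pulse parameters and derived
#' quantities such as the charge per pulse.
#'
#' @param object an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("voltages", function(object) standardGeneric("voltages"))

#' @rdname accessors
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("trialEvents", function(object) standardGeneric("trialEvents"))

#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(object) standardGeneric("spikeTimes"))

#' @rdname accessors
#' @export
setGeneric("onsets", function(object) standardGeneric("onsets"))

#' @rdname accessors
#' @export
setGeneric("chargePerPulse", function(object) standardGeneric("chargePerPulse"))

#' @rdname accessors
#' @export
setGeneric("rateValues", function(object) standardGeneric("rateValues"))

#' @rdname accessors
#' @export
setGeneric("binEdges", function(object) standardGeneric("binEdges"))

#' @rdname accessors
#' @export
setGeneric("binCenters", function(object) standardGeneric("binCenters"))

#' @rdname accessors
#' @export
setGeneric("freqValues", function(object) standardGeneric("freqValues"))

#' @rdname accessors
#' @export
setGeneric("klValue", function(object) standardGeneric("klValue"))

#' @rdname accessors
#' @export
setGeneric("csdValues", function(object) standardGeneric("csdValues"))

#' @rdname accessors
#' @export
setGeneric("channelR", function(object) standardGeneric("channelR"))

#' @rdname accessors
#' @export
setGeneric("shuffleR", function(object) standardGeneric("shuffleR"))

#' @rdname accessors
#' @export
setGeneric("sigmaValue", function(object) standardGeneric("sigmaValue"))

## ---- methods ----------------------------------------------------------------

#' @rdname accessors
setMethod("duration", "PressureStimulus",
          function(object) length(object@samples) * object@timeStep)
#' @rdname accessors
setMethod("duration", "SpikeTrainSet", function(object) object@duration)
#' @rdname accessors
setMethod("duration", "StimTrain", function(object) object@duration)
#' @rdname accessors
setMethod("duration", "RateProfile",
          function(object) diff(range(object@binEdges)))
#' @rdname accessors
setMethod("duration", "FrequencyProfile",
          function(object) length(object@freq) * object@timeStep)
#' @rdname accessors
setMethod("duration", "MultichannelRecording",
          function(object) ncol(object@voltages) / object@samplingRate)

#' @rdname accessors
setMethod("samplingRate", "MultichannelRecording",
          function(object) object@samplingRate)
#' @rdname accessors
setMethod("voltages", "MultichannelRecording", function(object) object@voltages)
#' @rdname accessors
setMethod("geometry", "MultichannelRecording", function(object) object@geometry)
#' @rdname accessors
setMethod("trialEvents", "MultichannelRecording",
          function(object) object@trialEvents)
#' @rdname accessors
setMethod("nChannels", "MultichannelRecording",
          function(object) object@geometry@nChannels)
#' @rdname accessors
setMethod("nChannels", "ProbeGeometry", function(object) object@nChannels)

#' @rdname accessors
setMethod("spikeTimes", "SpikeTrainSet", function(object) object@spikes)
#' @rdname accessors
setMethod("spikeTimes", "DetectedSpikes", function(object) object@times)
#' @rdname accessors
setMethod("spikeTimes", "GroundTruth", function(object) object@spikes)

#' @rdname accessors
setMethod("onsets", "StimTrain", function(object) object@onsets)
#' @rdname accessors
setMethod("chargePerPulse", "StimTrain",
          function(object) object@amplitudeUa * object@pulseWidthUs / 1000)

#' @rdname accessors
setMethod("rateValues", "RateProfile", function(object) object@rate)
#' @rdname accessors
setMethod("binEdges", "RateProfile", function(object) object@binEdges)
#' @rdname accessors
setMethod("binCenters", "RateProfile", function(object) {
  e <- object@binEdges
  (e[-1] + e[-length(e)]) / 2
})
#' @rdname accessors
setMethod("freqValues", "FrequencyProfile", function(object) object@freq)
#' @rdname accessors
setMethod("klValue", "DistributionComparison", function(object) object@kl)
#' @rdname accessors
setMethod("csdValues", "CSDMap", function(object) object@values)
#' @rdname accessors
setMethod("channelR", "CorrelationReport", function(object) object@channelR)
#' @rdname accessors
setMethod("shuffleR", "CorrelationReport", function(object) object@shuffleR)
#' @rdname accessors
setMethod("sigmaValue", "NoiseEstimate", function(object) object@sigma)

## ---- show -------------------------------------------------------------------

setMethod("show", "AfferentPopulation", function(object) {
  cat("AfferentPopulation:", nrow(object@units), "units,",
      "composition", object@composition, "\n")
  print(table(object@units$class))
})

setMethod("show", "PressureStimulus", function(object) {
  cat(sprintf("PressureStimulus: %.3f s at %.4g s/step, peak %.3g (+/- %.2g%% noise)\n",
              duration(object), object@timeStep, object@amplitude,
              100 * object@noiseFraction))
})

setMethod("show", "SpikeTrainSet", function(object) {
  n <- vapply(object@spikes, length, integer(1))
  cat(sprintf("SpikeTrainSet: %d units, %.2f s, %d spikes (mean rate %.2f /s)\n",
              length(n), object@duration, sum(n),
              mean(n) / object@duration))
})

setMethod("show", "RateProfile", function(object) {
  cat(sprintf("RateProfile: %d bins of %.4g s (%s), peak %.2f spikes/s, %d trials\n",
              length(object@rate), object@binEdges[2] - object@binEdges[1],
              object@binWidthMethod, max(object@rate), object@nTrials))
})

setMethod("show", "StimTrain", function(object) {
  q <- chargePerPulse(object)
  cat(sprintf("StimTrain [%s]: %d pulses over %.2f s, charge %.3g-%.3g nC/pulse\n",
              object@encoding, length(object@onsets), object@duration,
              if (length(q)) min(q) else NA, if (length(q)) max(q) else NA))
})

setMethod("show", "MultichannelRecording", function(object) {
  cat(sprintf("MultichannelRecording: %d channels x %.2f s at %g kHz (%s probe), %d trial events\n",
              nChannels(object), duration(object), object@samplingRate / 1000,
              object@geometry@layout, length(object@trialEvents)))
})

setMethod("show", "CSDMap", function(object) {
  cat(sprintf("CSDMap: %d channels x %d bins (%g ms), spacing %g um, normalized\n",
              nrow(object@values), ncol(object@values), object@timeBinMs,
              object@spacingUm))
})

setMethod("show", "DistributionComparison", function(object) {
  cat(sprintf("DistributionComparison: KL(%s) = %.4g nats (%d bins)\n",
              object@direction, object@kl, length(object@binEdges) - 1L))
})

setMethod("show", "CorrelationReport", function(object) {
  cat(sprintf("CorrelationReport: pooled r = %.3f (p = %.3g, CI [%.3f, %.3f]); median channel r = %.3f; %d shuffles\n",
              object@pooledR, object@pooledP, object@pooledCI[1],
              object@pooledCI[2], median(object@channelR, na.rm = TRUE),
              nrow(object@shuffleR)))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison: H = %.3f (df = %d), p = %.4g, f = %.3f\n",
              object@statistic, object@df, object@pValue, object@effectSizeF))
  print(object@groupSummary)
})

setMethod("show", "ChargeSafetyReport", function(object) {
  cat(sprintf("ChargeSafetyReport: limit %g nC, %d violation(s) -> %s\n",
              object@limitNc, length(object@violations),
              if (object@pass) "PASS" else "FAIL"))
})
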