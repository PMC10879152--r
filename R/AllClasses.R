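#' @import methods
#' @importFrom stats approx cor cor.test fft ks.test kruskal.test median
#'   p.adjust pchisq pnorm qnorm qqnorm quantile rexp rnorm rpois runif
#'   sd var IQR spec.pgram
#' @importFrom utils head tail read.csv write.csv
NULL

AFFERENT_CLASSES <- c("SA1", "SA2", "FA1", "FA2")
ENCODING_LABELS <- c("BIOM_SA1", "BIOM_SA2", "BIOM_FA1", "BIOM_FA2",
                     "BIOM_FULL", "TONIC", "LIN", "DISC", "SINUS_PW", "POISSON")

#' Ramp-and-hold pressure stimulus
#'
#' Sampled pressure trace (arbitrary pressure units) delivered to the foot
#' sole.  The peak of the noiseless trace equals \code{amplitude}; additive
#' environmental noise is bounded by \code{noiseFraction * amplitude} and the
#' trace is clipped at zero.
#'
#' @slot samples numeric vector of pressure values per time step.
#' @slot timeStep sample interval in seconds.
#' @slot amplitude nominal peak pressure.
#' @slot noiseFraction bound of additive noise as a fraction of the peak.
#' @exportClass PressureStimulus
setClass("PressureStimulus",
  representation(samples = "numeric", timeStep = "numeric",
                 amplitude = "numeric", noiseFraction = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@timeStep <= 0) msg <- c(msg, "timeStep must be positive")
    if (any(!is.finite(object@samples))) msg <- c(msg, "samples must be finite")
    if (any(object@samples < 0)) msg <- c(msg, "samples must be non-negative")
    lim <- object@amplitude * (1 + object@noiseFraction) + 1e-12
    if (length(object@samples) && max(object@samples) > lim)
      msg <- c(msg, "samples exceed amplitude * (1 + noiseFraction)")
    if (length(msg)) msg else TRUE
  })

#' Population of tactile afferent units
#'
#' Units of the four cutaneous mechanoreceptor classes (SA1, SA2, FA1, FA2)
#' placed on a 2-D foot-sole outline, each with its own rate-model parameters.
#'
#' @slot units data.frame with one row per unit: \code{class}, \code{x},
#'   \code{y} (mm), \code{gainStatic} (spikes/s per pressure unit),
#'   \code{gainDynamic} (spikes/s per pressure-unit/s), \code{gainAccel}
#'   (spikes/s per pressure-unit/s^2), \code{tauAdapt} (s),
#'   \code{saturation} and \code{spontaneous} (spikes/s).
#' @slot composition one of SA1, SA2, FA1, FA2, FULL.
#' @slot seed integer seed the population was drawn with.
#' @exportClass AfferentPopulation
setClass("AfferentPopulation",
  representation(units = "data.frame", composition = "character",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    need <- c("class", "x", "y", "gainStatic", "gainDynamic", "gainAccel",
              "tauAdapt", "saturation", "spontaneous")
    if (!all(need %in% names(object@units)))
      msg <- c(msg, "units is missing required columns")
    else {
      u <- object@units
      if (!all(u$class %in% AFFERENT_CLASSES))
        msg <- c(msg, "unknown afferent class in units")
      if (any(u$gainStatic < 0) || any(u$gainDynamic < 0) || any(u$gainAccel < 0))
        msg <- c(msg, "gains must be non-negative")
      if (any(u$saturation <= 0)) msg <- c(msg, "saturation must be positive")
      if (any(u$tauAdapt <= 0)) msg <- c(msg, "tauAdapt must be positive")
      if (object@composition %in% AFFERENT_CLASSES &&
          !all(u$class == object@composition))
        msg <- c(msg, "single-class population contains foreign classes")
    }
    if (!object@composition %in% c(AFFERENT_CLASSES, "FULL"))
      msg <- c(msg, "composition must be SA1, SA2, FA1, FA2 or FULL")
    if (length(msg)) msg else TRUE
  })

#' Set of spike trains from a simulated afferent population
#'
#' @slot spikes list of numeric vectors, one per unit, strictly increasing
#'   spike times in seconds within \code{[0, duration]}.
#' @slot unitClass afferent class per unit.
#' @slot duration trial duration in seconds.
#' @slot trial trial index.
#' @exportClass SpikeTrainSet
setClass("SpikeTrainSet",
  representation(spikes = "list", unitClass = "character",
                 duration = "numeric", trial = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@spikes) != length(object@unitClass))
      msg <- c(msg, "spikes and unitClass lengths differ")
    bad <- vapply(object@spikes, function(s) {
      length(s) && (is.unsorted(s, strictly = TRUE) ||
                    min(s) < 0 || max(s) > object@duration)
    }, logical(1))
    if (any(bad))
      msg <- c(msg, "spike times must be strictly increasing within [0, duration]")
    if (length(msg)) msg else TRUE
  })

#' Binned firing-rate profile (PSTH)
#'
#' @slot binEdges strictly increasing bin edges in seconds
#'   (length \code{nBins + 1}).
#' @slot rate firing rate per bin in spikes/s.
#' @slot nTrials number of trials (or units) pooled.
#' @slot binWidthMethod "fixed" or "freedman_diaconis".
#' @slot smoothing list with \code{kernel} and \code{width} (seconds), or
#'   empty when unsmoothed.
#' @exportClass RateProfile
setClass("RateProfile",
  representation(binEdges = "numeric", rate = "numeric", nTrials = "integer",
                 binWidthMethod = "character", smoothing = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@binEdges) != length(object@rate) + 1L)
      msg <- c(msg, "need length(binEdges) == length(rate) + 1")
    if (is.unsorted(object@binEdges, strictly = TRUE))
      msg <- c(msg, "binEdges must be strictly increasing")
    if (any(object@rate < 0)) msg <- c(msg, "rates must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Stimulation frequency profile
#'
#' @slot timeStep sample interval in seconds.
#' @slot freq instantaneous stimulation frequency in Hz per sample.
#' @slot fMin,fMax frequency bounds of the affine rate-to-frequency map (Hz).
#' @exportClass FrequencyProfile
setClass("FrequencyProfile",
  representation(timeStep = "numeric", freq = "numeric",
                 fMin = "numeric", fMax = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@fMin < 0) msg <- c(msg, "fMin must be >= 0")
    if (object@fMax < object@fMin) msg <- c(msg, "fMax must be >= fMin")
    tol <- 1e-9
    if (length(object@freq) &&
        (min(object@freq) < object@fMin - tol ||
         max(object@freq) > object@fMax + tol))
      msg <- c(msg, "freq samples must lie in [fMin, fMax]")
    if (length(msg)) msg else TRUE
  })

#' Charge-balanced biphasic stimulation pulse train
#'
#' Cathodic-first, charge-balanced symmetric square pulses.  The charge per
#' pulse is \code{amplitudeUa * pulseWidthUs / 1000} nC by construction.
#'
#' @slot onsets sorted pulse onset times in seconds.
#' @slot amplitudeUa per-pulse amplitude in microamperes.
#' @slot pulseWidthUs per-pulse (single-phase) width in microseconds.
#' @slot encoding one of the supported encoding labels.
#' @slot duration train span in seconds.
#' @exportClass StimTrain
setClass("StimTrain",
  representation(onsets = "numeric", amplitudeUa = "numeric",
                 pulseWidthUs = "numeric", encoding = "character",
                 duration = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@onsets)
    if (length(object@amplitudeUa) != n || length(object@pulseWidthUs) != n)
      msg <- c(msg, "amplitudeUa and pulseWidthUs must match onsets in length")
    if (is.unsorted(object@onsets)) msg <- c(msg, "onsets must be sorted")
    if (!object@encoding %in% ENCODING_LABELS)
      msg <- c(msg, "unknown encoding label")
    if (n > 1) {
      ipi <- diff(object@onsets)
      biphasic <- 2 * object@pulseWidthUs[-n] * 1e-6
      if (any(ipi <= biphasic))
        msg <- c(msg, "inter-pulse interval must exceed the biphasic pulse duration")
    }
    if (length(msg)) msg else TRUE
  })

#' Charge-safety validation report
#'
#' @slot limitNc charge limit per pulse in nC.
#' @slot violations indices of pulses exceeding the limit.
#' @slot pass TRUE iff there are no violations.
#' @exportClass ChargeSafetyReport
setClass("ChargeSafetyReport",
  representation(limitNc = "numeric", violations = "integer", pass = "logical"),
  validity = function(object) {
    if (object@pass != (length(object@violations) == 0L))
      "pass must be TRUE exactly when violations is empty" else TRUE
  })

#' Recording probe geometry
#'
#' @slot nChannels number of recording channels.
#' @slot layout "linear" (shaft) or "grid" (array).
#' @slot spacingUm inter-channel spacing in micrometres (linear layout).
#' @exportClass ProbeGeometry
setClass("ProbeGeometry",
  representation(nChannels = "integer", layout = "character",
                 spacingUm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@layout %in% c("linear", "grid"))
      msg <- c(msg, "layout must be 'linear' or 'grid'")
    if (object@layout == "linear" && object@spacingUm <= 0)
      msg <- c(msg, "spacing must be positive for a linear layout")
    if (object@nChannels < 1L) msg <- c(msg, "need at least one channel")
    if (length(msg)) msg else TRUE
  })

#' Multichannel extracellular recording
#'
#' @slot samplingRate sampling frequency in Hz.
#' @slot voltages channels x samples matrix in microvolts.
#' @slot geometry a \linkS4class{ProbeGeometry}.
#' @slot trialEvents stimulus/trial onset times in seconds.
#' @exportClass MultichannelRecording
setClass("MultichannelRecording",
  representation(samplingRate = "numeric", voltages = "matrix",
                 geometry = "ProbeGeometry", trialEvents = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@voltages) != object@geometry@nChannels)
      msg <- c(msg, "voltage rows must match the channel count")
    # row-wise so validity never allocates matrix-sized temporaries
    for (ch in seq_len(nrow(object@voltages)))
      if (anyNA(object@voltages[ch, ]) ||
          any(is.infinite(object@voltages[ch, ]))) {
        msg <- c(msg, "voltages must be finite")
        break
      }
    if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be positive")
    if (length(msg)) msg else TRUE
  })

#' Ground truth paired with a synthetic recording
#'
#' @slot spikes list of per-channel true spike times (s).
#' @slot artifactWindows two-column matrix of artifact start/end times (s).
#' @slot rateProfile the imposed drive rate profile (\linkS4class{RateProfile})
#'   or NULL for an electrical drive.
#' @slot driveLabel NATURAL, TONIC, POISSON or a BIOM_* label.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(spikes = "list", artifactWindows = "matrix",
                 rateProfile = "ANY", driveLabel = "character"))

#' Noise model for synthetic recordings
#'
#' @slot backgroundSd Gaussian background SD in microvolts.
#' @slot backgroundCornerHz corner frequency of the one-pole low-pass that
#'   shapes the background noise spectrum (extracellular noise is red);
#'   \code{Inf} gives white noise.
#' @slot lineAmplitudeUv amplitude per powerline harmonic (50, 100, ... Hz).
#' @slot driftAmplitudeUv slow drift amplitude in microvolts.
#' @slot driftFreqHz drift corner frequency in Hz.
#' @slot artifactRate large-artifact rate in events/s.
#' @slot artifactAmplitudeSd artifact amplitude in multiples of the
#'   background SD.
#' @slot artifactWidthMs artifact width in ms.
#' @exportClass NoiseConfig
setClass("NoiseConfig",
  representation(backgroundSd = "numeric", backgroundCornerHz = "numeric",
                 lineAmplitudeUv = "numeric",
                 driftAmplitudeUv = "numeric", driftFreqHz = "numeric",
                 artifactRate = "numeric", artifactAmplitudeSd = "numeric",
                 artifactWidthMs = "numeric"),
  validity = function(object) {
    amps <- c(object@backgroundSd, object@lineAmplitudeUv,
              object@driftAmplitudeUv, object@artifactRate,
              object@artifactAmplitudeSd)
    if (any(amps < 0)) "all amplitudes and rates must be >= 0" else TRUE
  })

#' Robust noise-level estimate
#'
#' @slot sigma estimated standard deviation (microvolts).
#' @slot method estimator name.
#' @exportClass NoiseEstimate
setClass("NoiseEstimate",
  representation(sigma = "numeric", method = "character"),
  validity = function(object)
    if (any(object@sigma < 0)) "sigma must be >= 0" else TRUE)

#' Threshold-crossing spike detections
#'
#' @slot times list of per-channel sorted detection times (s).
#' @slot thresholdUv signed threshold per channel (microvolts).
#' @slot sigmaUv robust noise SD per channel used for the threshold.
#' @slot polarity "negative" or "positive".
#' @slot deadTime enforced minimum separation between detections (s).
#' @exportClass DetectedSpikes
setClass("DetectedSpikes",
  representation(times = "list", thresholdUv = "numeric", sigmaUv = "numeric",
                 polarity = "character", deadTime = "numeric"))

#' Current source density map
#'
#' @slot values channels x time-bins CSD matrix, normalized so that the
#'   largest absolute value is 1.
#' @slot timeBinMs time bin in milliseconds.
#' @slot spacingUm electrode spacing in micrometres.
#' @exportClass CSDMap
setClass("CSDMap",
  representation(values = "matrix", timeBinMs = "numeric",
                 spacingUm = "numeric"),
  validity = function(object) {
    m <- max(abs(object@values))
    if (m > 0 && abs(m - 1) > 1e-9)
      "values must be normalized to max |value| = 1" else TRUE
  })

#' Histogram-based distribution comparison (KL divergence)
#'
#' @slot kl Kullback-Leibler divergence in nats.
#' @slot binEdges shared histogram bin edges.
#' @slot direction label "condition||reference".
#' @exportClass DistributionComparison
setClass("DistributionComparison",
  representation(kl = "numeric", binEdges = "numeric", direction = "character"),
  validity = function(object)
    if (object@kl < -1e-12) "KL divergence must be >= 0" else TRUE)

#' Channel-wise correlation report with shuffled-channel null
#'
#' @slot channelR per-channel Pearson r (NA where undefined).
#' @slot pooledR Pearson r over all channel x bin pairs.
#' @slot pooledP two-sided p-value for pooledR.
#' @slot pooledCI Fisher-z 95% confidence interval for pooledR.
#' @slot shuffleR nShuffles x channels matrix of null correlations.
#' @exportClass CorrelationReport
setClass("CorrelationReport",
  representation(channelR = "numeric", pooledR = "numeric", pooledP = "numeric",
                 pooledCI = "numeric", shuffleR = "matrix"),
  validity = function(object) {
    r <- c(object@channelR, object@pooledR, object@shuffleR)
    r <- r[!is.na(r)]
    if (length(r) && (min(r) < -1 - 1e-9 || max(r) > 1 + 1e-9))
      "correlations must lie in [-1, 1]" else TRUE
  })

#' Normalized cross-correlation between two rate profiles
#'
#' @slot lags lag values in seconds.
#' @slot values normalized cross-correlation per lag.
#' @slot peak maximal correlation.
#' @slot peakLag lag of the maximum (s).
#' @exportClass CrossCorrResult
setClass("CrossCorrResult",
  representation(lags = "numeric", values = "numeric", peak = "numeric",
                 peakLag = "numeric"),
  validity = function(object)
    if (abs(object@peak) > 1 + 1e-9) "peak must lie in [-1, 1]" else TRUE)

#' Nonparametric group comparison
#'
#' Kruskal-Wallis omnibus test with Dunn-style pairwise post-hocs and a
#' Cohen's f effect size derived from the rank epsilon-squared.
#'
#' @slot statistic omnibus H statistic (tie-corrected).
#' @slot df degrees of freedom.
#' @slot pValue omnibus p-value.
#' @slot pairwise data.frame of pairwise comparisons (z, raw and corrected p).
#' @slot effectSizeF Cohen's f from the rank epsilon-squared.
#' @slot groupSummary per-group n, median, mean and SD.
#' @exportClass GroupComparison
setClass("GroupComparison",
  representation(statistic = "numeric", df = "numeric", pValue = "numeric",
                 pairwise = "data.frame", effectSizeF = "numeric",
                 groupSummary = "data.frame"),
  validity = function(object) {
    if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
      "p-value must lie in [0, 1]" else TRUE
  })
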