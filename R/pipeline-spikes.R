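#' Threshold-crossing spike detection
#'
#' Detects multi-unit spikes as crossings of a signed robust threshold on
#' the spike-band signal: \code{-multiple * sigma} for negative polarity
#' (the convention for intraspinal recordings, \code{multiple = 3}; DRG
#' recordings use 4) where \code{sigma = median(|x|)/0.6745} per channel.
#' When several datasets from one recording site are analysed together the
#' threshold sigma should be estimated on their concatenation and passed via
#' \code{sigma}.  A dead time (default 1 ms) keeps only the first crossing
#' of each excursion.
#'
#' @param recording a \linkS4class{MultichannelRecording}, band-passed to
#'   the spike band.
#' @param multiple threshold in robust-SD multiples.
#' @param polarity "negative" (default) or "positive".
#' @param deadTime minimum separation between detections (s), must be
#'   positive.
#' @param sigma optional per-channel sigma vector (e.g. estimated on a
#'   concatenation of recordings); estimated from \code{recording} when
#'   omitted.
#' @return a \linkS4class{DetectedSpikes}.
#' @export
detectSpikes <- function(recording, multiple = 3,
                         polarity = c("negative", "positive"),
                         deadTime = 0.001, sigma = NULL) {
  polarity <- match.arg(polarity)
  if (deadTime <= 0) stop("deadTime must be positive")
  fs <- recording@samplingRate
  v <- recording@voltages
  sigma <- sigma %||% channelSigmas(recording)
  if (length(sigma) == 1L) sigma <- rep(sigma, nrow(v))
  dead <- round(deadTime * fs)
  times <- vector("list", nrow(v))
  thr <- numeric(nrow(v))
  for (ch in seq_len(nrow(v))) {
    x <- v[ch, ]
    if (polarity == "negative") {
      th <- -multiple * sigma[ch]
      below <- x <= th
    } else {
      th <- multiple * sigma[ch]
      below <- x >= th
    }
    thr[ch] <- th
    # first samples of threshold excursions
    cross <- which(below & !c(FALSE, below[-length(below)]))
    if (length(cross) > 1) {
      keep <- logical(length(cross))
      keep[1] <- TRUE
      last <- cross[1]
      for (i in seq_along(cross)[-1]) {
        if (cross[i] - last >= dead) {
          keep[i] <- TRUE
          last <- cross[i]
        }
      }
      cross <- cross[keep]
    }
    times[[ch]] <- (cross - 1) / fs
  }
  new("DetectedSpikes", times = times, thresholdUv = thr, sigmaUv = sigma,
      polarity = polarity, deadTime = deadTime)
}

#' Freedman-Diaconis histogram bin width
#'
#' \code{2 * IQR(x) * N^(-1/3)}; used to choose PSTH bin widths from the
#' spike-time sample itself.
#'
#' @param samples numeric sample (N >= 2).
#' @return bin width, same units as \code{samples}.
#' @examples
#' fdBinWidth(c(0, 1, 1, 1, 2, 2, 2, 3))  # IQR 1, N 8 -> exactly 1
#' @export
fdBinWidth <- function(samples) {
  n <- length(samples)
  if (n < 2) stop("need at least two samples")
  iqr <- IQR(samples)
  if (iqr == 0)
    stop("degenerate sample (IQR = 0); fall back to a fixed bin width")
  2 * iqr * n^(-1 / 3)
}

#' Peri-stimulus time histogram
#'
#' Bins spikes relative to repeated stimulus onsets, pooled over trials.
#' The rate in each bin is \code{count / (nTrials * binWidth)}.
#'
#' @param spikes numeric spike times (s), or a list of per-channel vectors
#'   which are pooled.
#' @param trialOnsets stimulus onset times (s), at least one.
#' @param window length-2 analysis window relative to onset (s).
#' @param binWidth bin width (s), or "fd" to derive it from the pooled
#'   relative spike times via \code{\link{fdBinWidth}}.
#' @return a \linkS4class{RateProfile}; the spike raster (data.frame with
#'   \code{trial} and \code{time}) is attached as attribute
#'   \code{"raster"}.
#' @export
buildPsth <- function(spikes, trialOnsets, window, binWidth = 0.01) {
  if (!length(trialOnsets)) stop("need at least one trial")
  if (is.list(spikes)) spikes <- sort(unlist(spikes, use.names = FALSE))
  rel <- unlist(lapply(seq_along(trialOnsets), function(i) {
    r <- spikes - trialOnsets[i]
    r[r >= window[1] & r <= window[2]]
  }), use.names = FALSE)
  trialIdx <- unlist(lapply(seq_along(trialOnsets), function(i) {
    r <- spikes - trialOnsets[i]
    rep(i, sum(r >= window[1] & r <= window[2]))
  }), use.names = FALSE)
  method <- "fixed"
  if (identical(binWidth, "fd")) {
    binWidth <- fdBinWidth(rel)
    method <- "freedman_diaconis"
  }
  edges <- seq(window[1], window[2], by = binWidth)
  if (max(edges) < window[2] - 1e-12)
    edges <- c(edges, max(edges) + binWidth)
  counts <- binCount(rel, edges)
  prof <- new("RateProfile", binEdges = edges,
              rate = counts / (length(trialOnsets) * binWidth),
              nTrials = length(trialOnsets), binWidthMethod = method,
              smoothing = list())
  attr(prof, "raster") <- data.frame(trial = trialIdx, time = rel)
  prof
}

#' Summed normalized activity per condition
#'
#' Each condition's PSTH is normalized to \code{[0, 1]} by its own maximum,
#' the normalized bins are summed, and the sums are divided by the largest
#' sum, so exactly one condition scores 1.  The score is inversely related
#' to the variance of the PSTH: a flat (tonically driven) response maximizes
#' it, while transient responses score low.
#'
#' @param psths named list of \linkS4class{RateProfile}s (>= 2 conditions).
#' @return named numeric vector in \code{(0, 1]}.
#' @export
summedNormalizedActivity <- function(psths) {
  if (length(psths) < 2) stop("need at least two conditions")
  sums <- vapply(psths, function(p) {
    r <- rateValues(p)
    m <- max(r)
    if (m <= 0) stop("all-zero PSTH")
    sum(r / m)
  }, numeric(1))
  sums / max(sums)
}

#' Normalized cross-correlation of two rate profiles
#'
#' Mean-subtracted, unit-normalized cross-correlation between two profiles
#' on the same bin grid; reports the full sequence, the peak and its lag.
#' Used to quantify how faithfully the stimulation frequency profile is
#' transmitted into the evoked PSTH.
#'
#' @param a,b \linkS4class{RateProfile}s with equal bin widths.
#' @param maxLag maximum lag (s); defaults to half the shorter profile.
#' @return a \linkS4class{CrossCorrResult}.
#' @export
xcorrProfiles <- function(a, b, maxLag = NULL) {
  bwA <- a@binEdges[2] - a@binEdges[1]
  bwB <- b@binEdges[2] - b@binEdges[1]
  if (abs(bwA - bwB) > 1e-9) stop("profiles have different bin widths")
  x <- rateValues(a)
  y <- rateValues(b)
  n <- min(length(x), length(y))
  x <- x[seq_len(n)] - mean(x[seq_len(n)])
  y <- y[seq_len(n)] - mean(y[seq_len(n)])
  maxLagBins <- if (is.null(maxLag)) floor(n / 2) else round(maxLag / bwA)
  maxLagBins <- min(maxLagBins, n - 1L)
  denom <- sqrt(sum(x^2) * sum(y^2))
  if (denom == 0) stop("constant profile: correlation undefined")
  lags <- seq(-maxLagBins, maxLagBins)
  vals <- vapply(lags, function(k) {
    if (k >= 0) sum(x[seq_len(n - k)] * y[seq_len(n - k) + k]) / denom
    else sum(x[seq_len(n + k) - k] * y[seq_len(n + k)]) / denom
  }, numeric(1))
  pk <- which.max(vals)
  new("CrossCorrResult", lags = lags * bwA, values = vals,
      peak = vals[pk], peakLag = lags[pk] * bwA)
}

#' Afferent-volley amplitude check
#'
#' TRUE iff the peak-to-peak amplitude of the response segment exceeds
#' \code{mean(baseline) + k * sd(baseline)}; the rule used to titrate the
#' stimulation amplitude until a robust afferent volley is evoked.
#'
#' @param baseline resting-signal segment (non-empty).
#' @param response response segment (non-empty).
#' @param k SD multiple, default 2.5.
#' @return logical.
#' @export
volleyCheck <- function(baseline, response, k = 2.5) {
  if (!length(baseline) || !length(response)) stop("empty segment")
  p2p <- diff(range(response))
  s <- if (length(baseline) > 1) sd(baseline) else 0
  p2p > mean(baseline) + k * s
}
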