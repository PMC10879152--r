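#' Trigger-averaged LFP
#'
#' Averages event-aligned windows of an LFP-band recording per channel.
#'
#' @param recording a \linkS4class{MultichannelRecording} (LFP band).
#' @param events event/trial onset times (s), at least one.
#' @param window length-2 window relative to each event (s); every aligned
#'   window must lie within the recording.
#' @return channels x samples matrix of the average, with attribute
#'   \code{"samplingRate"}.
#' @export
triggerAverageLfp <- function(recording, events, window) {
  if (!length(events)) stop("need at least one event")
  fs <- recording@samplingRate
  v <- recording@voltages
  i0 <- round((events + window[1]) * fs) + 1L
  len <- round((window[2] - window[1]) * fs)
  if (any(i0 < 1L) || any(i0 + len - 1L > ncol(v)))
    stop("window exceeds recording bounds")
  acc <- matrix(0, nrow(v), len)
  for (k in seq_along(events))
    acc <- acc + v[, i0[k]:(i0[k] + len - 1L), drop = FALSE]
  avg <- acc / length(events)
  attr(avg, "samplingRate") <- fs
  avg
}

#' Select the most active channels by trigger-averaged LFP amplitude
#'
#' Ranks channels by the peak-to-peak amplitude of their trigger-averaged
#' LFP and returns the top \code{k}; the selection rule used to pick the
#' channels with clear evoked responses before comparing LFP amplitude
#' distributions.
#'
#' @param avgLfp channels x samples trigger-averaged LFP.
#' @param k number of channels to keep (default 12).
#' @return integer vector of channel indices, strongest first.
#' @export
mostActiveChannels <- function(avgLfp, k = 12) {
  p2p <- apply(avgLfp, 1, function(x) diff(range(x)))
  head(order(p2p, decreasing = TRUE), k)
}

#' Kullback-Leibler divergence between LFP amplitude distributions
#'
#' Histograms both sample sets on shared bin edges spanning their pooled
#' range, regularizes the normalized histograms with an additive
#' \code{epsilon} and returns \code{KL(condition || reference)} in nats.
#' The reference is conventionally the natural-touch condition: the larger
#' the divergence, the more the condition's LFP amplitude distribution
#' deviates from the naturally evoked one.
#'
#' @param samplesCondition,samplesReference numeric amplitude samples
#'   (non-empty).
#' @param nBins number of shared histogram bins (>= 2), default 50.
#' @param epsilon additive histogram regularizer, default 1e-10.
#' @param direction label stored on the result.
#' @return a \linkS4class{DistributionComparison}.
#' @export
klLfpAmplitudes <- function(samplesCondition, samplesReference, nBins = 50,
                            epsilon = 1e-10,
                            direction = "condition||reference") {
  if (!length(samplesCondition) || !length(samplesReference))
    stop("both sample sets must be non-empty")
  if (nBins < 2) stop("need at least two bins")
  rng <- range(c(samplesCondition, samplesReference))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = nBins + 1L)
  p <- binCount(samplesCondition, edges) / length(samplesCondition)
  q <- binCount(samplesReference, edges) / length(samplesReference)
  p <- p + epsilon; p <- p / sum(p)
  q <- q + epsilon; q <- q / sum(q)
  kl <- sum(p * log(p / q))
  new("DistributionComparison", kl = max(kl, 0), binEdges = edges,
      direction = direction)
}

#' Current source density along a linear probe
#'
#' Estimates the CSD as the negative second spatial difference of the
#' trigger-averaged potential, \code{-(phi[j-1] - 2 phi[j] + phi[j+1]) /
#' dz^2}, with duplicated-edge boundary handling, then averages within time
#' bins (100 ms for electrical stimulation, 40 ms for natural touch) and
#' normalizes the map so its largest absolute value is 1.
#'
#' @param avgLfp channels x samples trigger-averaged LFP (>= 3 channels)
#'   with a \code{"samplingRate"} attribute, or pass \code{samplingRate}.
#' @param spacingUm electrode spacing (um).
#' @param timeBinMs time bin (ms).
#' @param samplingRate sampling rate (Hz) of \code{avgLfp}.
#' @return a \linkS4class{CSDMap}.
#' @export
computeCsd <- function(avgLfp, spacingUm, timeBinMs,
                       samplingRate = attr(avgLfp, "samplingRate")) {
  if (nrow(avgLfp) < 3) stop("CSD needs at least 3 channels")
  if (is.null(samplingRate)) stop("samplingRate is required")
  dz <- spacingUm
  padded <- rbind(avgLfp[1, ], avgLfp, avgLfp[nrow(avgLfp), ])
  nCh <- nrow(avgLfp)
  csd <- -(padded[seq_len(nCh), , drop = FALSE] -
             2 * padded[seq_len(nCh) + 1L, , drop = FALSE] +
             padded[seq_len(nCh) + 2L, , drop = FALSE]) / dz^2
  binSamp <- max(1L, round(timeBinMs / 1000 * samplingRate))
  nBins <- floor(ncol(csd) / binSamp)
  if (nBins < 1) stop("time bin longer than the signal")
  binned <- vapply(seq_len(nBins), function(b) {
    cols <- ((b - 1L) * binSamp + 1L):(b * binSamp)
    rowMeans(csd[, cols, drop = FALSE])
  }, numeric(nCh))
  m <- max(abs(binned))
  if (m > 0) binned <- binned / m
  new("CSDMap", values = binned, timeBinMs = timeBinMs, spacingUm = spacingUm)
}

#' Channel-wise CSD correlation with a shuffled-channel null
#'
#' Pearson correlation between two (normalized) CSD maps, channel by channel
#' across time bins, plus a pooled correlation over all channel x bin pairs
#' with its p-value and Fisher-z 95% CI.  The null control permutes the
#' channel order of the first map (seeded) \code{nShuffles} times and
#' recomputes the per-channel correlations: genuine spatial correspondence
#' between conditions vanishes under the permutation, so the shuffled
#' correlations concentrate around zero.
#'
#' @param csdA,csdB \linkS4class{CSDMap}s (or bare matrices) of equal shape.
#' @param nShuffles number of channel permutations, default 100.
#' @param seed integer seed for the permutations.
#' @return a \linkS4class{CorrelationReport}.  Channels with zero variance
#'   in either map get NA (skipped in summaries).
#' @export
channelwiseCorr <- function(csdA, csdB, nShuffles = 100, seed = 1) {
  a <- if (is(csdA, "CSDMap")) csdA@values else csdA
  b <- if (is(csdB, "CSDMap")) csdB@values else csdB
  if (!all(dim(a) == dim(b))) stop("CSD maps must have the same shape")
  nCh <- nrow(a)
  rowR <- function(m1, m2) {
    vapply(seq_len(nrow(m1)), function(ch) {
      x <- m1[ch, ]; y <- m2[ch, ]
      if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
    }, numeric(1))
  }
  chanR <- rowR(a, b)
  av <- as.vector(a); bv <- as.vector(b)
  pooled <- suppressWarnings(cor.test(av, bv))
  nPair <- length(av)
  zr <- atanh(max(min(pooled$estimate, 1 - 1e-15), -1 + 1e-15))
  se <- 1 / sqrt(nPair - 3)
  ci <- tanh(zr + c(-1, 1) * qnorm(0.975) * se)
  shuffle <- withSeed(seed, {
    t(vapply(seq_len(nShuffles), function(s) {
      rowR(a[sample(nCh), , drop = FALSE], b)
    }, numeric(nCh)))
  })
  new("CorrelationReport", channelR = chanR,
      pooledR = unname(pooled$estimate), pooledP = pooled$p.value,
      pooledCI = ci, shuffleR = shuffle)
}

#' Empirical CDF points of matched and shuffled channel correlations
#'
#' @param report a \linkS4class{CorrelationReport}.
#' @return list of two data.frames (\code{matched}, \code{shuffled}) with
#'   sorted correlation values and their cumulative probabilities.
#' @export
correlationCdfs <- function(report) {
  mk <- function(r) {
    r <- sort(r[!is.na(r)])
    data.frame(r = r, cdf = seq_along(r) / length(r))
  }
  list(matched = mk(report@channelR), shuffled = mk(as.vector(report@shuffleR)))
}

#' Along-probe LFP similarity
#'
#' Pearson correlation between a reference channel (default the first, most
#' dorsal one) of the trigger-averaged LFP and every other channel; with
#' naturally evoked activity the similarity decays along the probe, while
#' synchronized electrically evoked volleys keep it high throughout.
#'
#' @param avgLfp channels x samples trigger-averaged LFP (>= 2 channels).
#' @param referenceChannel reference channel index, default 1.
#' @return numeric vector of per-channel correlations (1 at the reference),
#'   with \code{median} and \code{quartiles} (of the non-reference channels)
#'   as attributes.
#' @export
alongProbeCorr <- function(avgLfp, referenceChannel = 1) {
  if (nrow(avgLfp) < 2) stop("need at least two channels")
  ref <- avgLfp[referenceChannel, ]
  if (sd(ref) == 0) stop("constant reference channel")
  r <- vapply(seq_len(nrow(avgLfp)), function(ch) {
    y <- avgLfp[ch, ]
    if (sd(y) == 0) NA_real_ else cor(ref, y)
  }, numeric(1))
  others <- r[-referenceChannel]
  attr(r, "median") <- median(others, na.rm = TRUE)
  attr(r, "quartiles") <- quantile(others, c(0.25, 0.75), na.rm = TRUE,
                                   names = FALSE)
  r
}
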