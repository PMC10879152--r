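#' Robust noise-level estimate
#'
#' Estimates the background noise standard deviation as
#' \code{median(|x|) / 0.6745}, the robust estimator that is insensitive to
#' the (sparse) spike waveforms riding on the noise.
#'
#' @param x numeric signal (non-empty).
#' @return a \linkS4class{NoiseEstimate}.
#' @examples
#' sigmaValue(robustSigma(rnorm(1e4)))   # close to 1
#' @export
robustSigma <- function(x) {
  if (!length(x)) stop("empty input")
  new("NoiseEstimate", sigma = median(abs(x)) / 0.6745,
      method = "robust-median")
}

#' Per-channel robust noise SD of a recording
#'
#' @param recording a \linkS4class{MultichannelRecording} (or a matrix).
#' @return numeric vector of per-channel sigma estimates.
#' @export
channelSigmas <- function(recording) {
  v <- if (is(recording, "MultichannelRecording")) recording@voltages
       else recording
  # row loop, not apply(): apply would transpose the (possibly huge) matrix
  vapply(seq_len(nrow(v)), function(ch) median(abs(v[ch, ])) / 0.6745,
         numeric(1))
}

# Apply a signal::filtfilt pass to every channel of a recording (or to a bare
# numeric vector), preserving length and channel count.
applyFiltfilt <- function(x, filt) {
  if (is(x, "MultichannelRecording")) {
    v <- x@voltages
    # write into a fresh single-reference matrix so the row assignments
    # never re-copy the full input
    out <- matrix(0, nrow(v), ncol(v))
    for (ch in seq_len(nrow(v))) {
      y <- signal::filtfilt(filt, v[ch, ])
      out[ch, ] <- y
    }
    x@voltages <- out
    x
  } else {
    signal::filtfilt(filt, x)
  }
}

#' Comb filter at the powerline frequency and its harmonics
#'
#' Cascade of zero-phase second-order Butterworth band-stops centred at
#' \code{baseHz}, \code{2 baseHz}, ... up to \code{maxHarmonicHz} (default:
#' the Nyquist frequency).  Each notch has width \code{f0 / q}.  Attenuation
#' at the notch centres exceeds 30 dB while passband signals a quarter
#' octave away are essentially untouched.
#'
#' @param x a \linkS4class{MultichannelRecording} or numeric vector.
#' @param samplingRate sampling rate (Hz); taken from the recording when
#'   omitted.
#' @param baseHz powerline frequency, default 50.
#' @param q notch quality factor (centre frequency / width), default 35.
#' @param maxHarmonicHz highest harmonic to notch; defaults to Nyquist.
#' @return the filtered input, same class and length.
#' @export
combNotch <- function(x, samplingRate = NULL, baseHz = 50, q = 35,
                      maxHarmonicHz = NULL) {
  fs <- samplingRate %||%
    (if (is(x, "MultichannelRecording")) x@samplingRate else
       stop("samplingRate is required for a bare vector"))
  if (fs <= 2 * baseHz) stop("sampling rate too low for a comb at ", baseHz)
  nyq <- fs / 2
  top <- min(maxHarmonicHz %||% nyq, nyq * 0.999)
  freqs <- seq(baseHz, top, by = baseHz)
  for (f0 in freqs) {
    bw <- f0 / q / 2
    filt <- signal::butter(2, c(f0 - bw, f0 + bw) / nyq, type = "stop")
    x <- applyFiltfilt(x, filt)
  }
  x
}

#' Zero-phase Butterworth high-pass
#'
#' Removes drift and DC with a 3rd-order Butterworth high-pass (default
#' 30 Hz cutoff), applied forward-backward so trigger-averaged responses are
#' not delayed.
#'
#' @param x a \linkS4class{MultichannelRecording} or numeric vector.
#' @param cutoff cutoff frequency (Hz).
#' @param order filter order (per pass).
#' @param samplingRate required for a bare vector.
#' @return the filtered input.
#' @export
butterHighpass <- function(x, cutoff = 30, order = 3, samplingRate = NULL) {
  fs <- samplingRate %||%
    (if (is(x, "MultichannelRecording")) x@samplingRate else
       stop("samplingRate is required for a bare vector"))
  if (cutoff >= fs / 2) stop("cutoff must be below Nyquist")
  filt <- signal::butter(order, cutoff / (fs / 2), type = "high")
  applyFiltfilt(x, filt)
}

#' Zero-phase Butterworth band-pass
#'
#' 3rd-order band-pass used to isolate the LFP band (30-300 Hz) or the
#' spike band (800-5000 Hz).
#'
#' @param x a \linkS4class{MultichannelRecording} or numeric vector.
#' @param band numeric length-2 band (Hz), strictly inside (0, Nyquist).
#' @param order filter order (per pass).
#' @param samplingRate required for a bare vector.
#' @return the filtered input.
#' @export
bandExtract <- function(x, band, order = 3, samplingRate = NULL) {
  fs <- samplingRate %||%
    (if (is(x, "MultichannelRecording")) x@samplingRate else
       stop("samplingRate is required for a bare vector"))
  if (length(band) != 2 || band[1] <= 0 || band[2] >= fs / 2 ||
      band[1] >= band[2])
    stop("band must lie strictly inside (0, Nyquist)")
  filt <- signal::butter(order, band / (fs / 2), type = "pass")
  applyFiltfilt(x, filt)
}

#' Blank high-amplitude artifacts
#'
#' Detects artifacts as excursions beyond \code{multiple} robust SDs
#' (default 15) of each channel and zeroes the affected stretch padded by
#' \code{padMs} (default 10 ms) before the first and after the last
#' threshold crossing of each artifact.  Crossings closer than twice the pad
#' are treated as one artifact.
#'
#' @param recording a \linkS4class{MultichannelRecording}.
#' @param multiple artifact threshold in robust-SD multiples.
#' @param padMs zero-padding around each artifact (ms).
#' @return list with the blanked \code{recording} and \code{windows}, a
#'   per-channel list of two-column matrices of blanked intervals (s).
#' @export
blankArtifacts <- function(recording, multiple = 15, padMs = 10) {
  fs <- recording@samplingRate
  pad <- round(padMs / 1000 * fs)
  v <- recording@voltages
  windows <- vector("list", nrow(v))
  for (ch in seq_len(nrow(v))) {
    x <- v[ch, ]
    sig <- median(abs(x)) / 0.6745
    cross <- which(abs(x) > multiple * sig)
    if (!length(cross)) {
      windows[[ch]] <- matrix(numeric(0), ncol = 2)
      next
    }
    gap <- which(diff(cross) > 2 * pad)
    starts <- cross[c(1L, gap + 1L)]
    ends <- cross[c(gap, length(cross))]
    i0 <- pmax(1L, starts - pad)
    i1 <- pmin(length(x), ends + pad)
    for (k in seq_along(i0)) x[i0[k]:i1[k]] <- 0
    v[ch, ] <- x
    windows[[ch]] <- cbind(start = (i0 - 1) / fs, end = i1 / fs)
  }
  recording@voltages <- v
  list(recording = recording, windows = windows)
}

#' Decimate a recording
#'
#' Anti-alias low-pass (8th-order Chebyshev via \code{signal::decimate})
#' followed by subsampling; used to move LFP-band analyses onto a cheaper
#' sampling grid.
#'
#' @param recording a \linkS4class{MultichannelRecording}.
#' @param factor integer decimation factor.
#' @return a \linkS4class{MultichannelRecording} at
#'   \code{samplingRate / factor}.
#' @export
decimateRecording <- function(recording, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1L) return(recording)
  v <- recording@voltages
  out <- NULL
  for (ch in seq_len(nrow(v))) {
    y <- signal::decimate(v[ch, ], factor)
    if (is.null(out)) out <- matrix(0, nrow(v), length(y))
    out[ch, ] <- y
  }
  recording@voltages <- out
  recording@samplingRate <- recording@samplingRate / factor
  recording
}
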