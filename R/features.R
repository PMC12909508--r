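# Spectral band features shared by the fuzzy index and the localizer.

.EEG_BANDS <- list(delta = c(0.5, 4), theta = c(4, 8),
                   alpha = c(8, 13), beta = c(13, 30))

.LOBE_ORDER <- c("frontal", "temporal", "parietal", "occipital")

# Periodogram of one channel (two-sided power, positive frequencies).
.periodogram <- function(x, fs) {
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  k <- seq_len(n %/% 2 + 1)
  list(freq = (k - 1) * fs / n, power = p[k])
}

#' Band power of a signal
#'
#' Periodogram power inside `band`; by default as a fraction of the
#' total power in `total` (0.5-30 Hz).  With `relative = FALSE` the
#' absolute in-band power is returned (the right scale for comparing
#' the same band across channels, e.g. for [deriveLobeLabel()] scores).
#'
#' @param x numeric vector.
#' @param samplingRate sampling rate in Hz.
#' @param band c(low, high) in Hz.
#' @param total reference band in Hz (ignored when `relative = FALSE`).
#' @param relative divide by the total-band power (default TRUE).
#' @return relative power in `[0, 1]` (0 for an all-zero signal), or
#'   absolute in-band power.
#' @export
bandPower <- function(x, samplingRate, band, total = c(0.5, 30),
                      relative = TRUE) {
  pg <- .periodogram(x, samplingRate)
  inBand <- pg$freq >= band[1] & pg$freq <= band[2]
  if (!relative) return(sum(pg$power[inBand]))
  inTotal <- pg$freq >= total[1] & pg$freq <= total[2]
  tot <- sum(pg$power[inTotal])
  if (tot <= 0) return(0)
  sum(pg$power[inBand & inTotal]) / tot
}

#' Normalized spectral entropy of a signal
#'
#' Shannon entropy of the normalized periodogram over 0.5-30 Hz, divided
#' by `log(nBins)` so the result lies in `[0, 1]` (1 = flat spectrum).
#'
#' @inheritParams bandPower
#' @return scalar in `[0, 1]`.
#' @export
spectralEntropy <- function(x, samplingRate, total = c(0.5, 30)) {
  pg <- .periodogram(x, samplingRate)
  keep <- pg$freq >= total[1] & pg$freq <= total[2]
  p <- pg$power[keep]
  s <- sum(p)
  if (s <= 0) return(1)
  p <- p / s
  p <- p[p > 0]
  -sum(p * log(p)) / log(sum(keep))
}

#' Fuzzy input features of a segment
#'
#' Channel-averaged relative alpha power, relative delta power and
#' normalized spectral entropy — the three crisp inputs of the fuzzy
#' seizure-activity index.
#'
#' @param segment channels x samples matrix.
#' @param samplingRate sampling rate in Hz.
#' @return named numeric vector `c(alpha, delta, entropy)`.
#' @export
segmentFuzzyFeatures <- function(segment, samplingRate) {
  a <- mean(apply(segment, 1, bandPower, samplingRate, .EEG_BANDS$alpha))
  d <- mean(apply(segment, 1, bandPower, samplingRate, .EEG_BANDS$delta))
  e <- mean(apply(segment, 1, spectralEntropy, samplingRate))
  c(alpha = a, delta = d, entropy = e)
}

#' Per-lobe band-power sequence of a segment
#'
#' Splits the segment into `nSub` equal sub-windows and computes, per
#' sub-window, the relative power of the four canonical bands (delta,
#' theta, alpha, beta) averaged over the channels of each lobe — the
#' 16-dimensional step input of the lobe localizer.
#'
#' @param segment channels x samples matrix.
#' @param channelNames channel names (mapped to lobes by
#'   [mapChannelToLobe()]).
#' @param samplingRate sampling rate in Hz.
#' @param nSub number of sub-windows (default 8).
#' @return `nSub` x 16 matrix (sub-windows in rows; columns ordered
#'   band-major: delta.frontal, delta.temporal, ...).
#' @export
lobeBandSequence <- function(segment, channelNames, samplingRate, nSub = 8L) {
  lobes <- vapply(channelNames, mapChannelToLobe, "")
  n <- ncol(segment)
  bounds <- floor(seq(0, n, length.out = nSub + 1))
  out <- matrix(0, nSub, length(.EEG_BANDS) * length(.LOBE_ORDER))
  for (s in seq_len(nSub)) {
    sub <- segment[, (bounds[s] + 1):bounds[s + 1], drop = FALSE]
    col <- 0L
    for (b in .EEG_BANDS) {
      for (lb in .LOBE_ORDER) {
        col <- col + 1L
        chans <- which(lobes == lb)
        out[s, col] <- if (length(chans)) {
          mean(apply(sub[chans, , drop = FALSE], 1, bandPower,
                     samplingRate, b))
        } else 0
      }
    }
  }
  out
}
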