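# Training-set-only signal augmentation and STFT spectrogram images.
#
# Six length-preserving transforms operate on channels x samples
# segments.  Spectrograms are magnitude STFTs (256-sample Hamming
# window, 256-point FFT, hop 128) cropped to 0-30 Hz, averaged across
# channels, log-scaled, min-max normalized and bilinearly resized to the
# model input shape.

.AUGMENT_TRANSFORMS <- c("noise_injection", "polarity_inversion",
                         "time_shift", "time_stretch", "pitch_scale",
                         "random_gain")

#' Specification of one augmentation transform
#'
#' @param transform one of `noise_injection`, `polarity_inversion`,
#'   `time_shift`, `time_stretch`, `pitch_scale`, `random_gain`.
#' @param targetSnrDb signal-to-noise ratio of injected white noise (dB).
#' @param shiftSec circular time shift in seconds.
#' @param stretchFactor time-stretch factor (1 = identity).
#' @param semitones pitch scaling in semitones (0 = identity).
#' @param gainDb gain in dB (0 = identity).
#' @param seed RNG seed for stochastic transforms.
#' @return a list of class `"AugmentSpec"`.
#' @export
augmentSpec <- function(transform, targetSnrDb = 10, shiftSec = 0.1,
                        stretchFactor = 1.05, semitones = 1, gainDb = 3,
                        seed = 1L) {
  if (!transform %in% .AUGMENT_TRANSFORMS)
    stop("unknown transform: ", transform)
  structure(list(transform = transform, targetSnrDb = targetSnrDb,
                 shiftSec = shiftSec, stretchFactor = stretchFactor,
                 semitones = semitones, gainDb = gainDb,
                 seed = as.integer(seed)),
            class = "AugmentSpec")
}

# Length-preserving index-scaling resample (linear interpolation,
# edge-padded); exact identity at factor 1.
.resampleKeepLength <- function(x, factor) {
  if (factor == 1) return(x)
  n <- length(x)
  idx <- 1 + (seq_len(n) - 1) * factor
  approx(seq_len(n), x, xout = pmin(idx, n), rule = 2)$y
}

#' Apply one augmentation transform to a segment
#'
#' All transforms preserve the segment shape; stochastic ones are
#' deterministic under the spec seed.  Noise injection scales the noise
#' so the realized SNR equals `targetSnrDb` exactly; pitch scaling is
#' spectral resampling (rate-preserving frequency scaling by
#' `2^(semitones/12)`).
#'
#' @param segment channels x samples numeric matrix.
#' @param spec an [augmentSpec()].
#' @return the transformed matrix, same dimensions.
#' @export
augmentSignal <- function(segment, spec) {
  stopifnot(is.matrix(segment), nrow(segment) >= 1, ncol(segment) >= 1,
            inherits(spec, "AugmentSpec"))
  out <- segment
  n <- ncol(segment)
  switch(spec$transform,
    noise_injection = {
      noise <- withSeed(spec$seed,
                        matrix(rnorm(length(segment)), nrow(segment)))
      ps <- mean(segment^2)
      pnTarget <- ps / 10^(spec$targetSnrDb / 10)
      noise <- noise * sqrt(pnTarget / mean(noise^2))
      out <- segment + noise
    },
    polarity_inversion = { out <- -segment },
    time_shift = {
      fs <- attr(segment, "samplingRate") %||% 256
      k <- round(spec$shiftSec * fs) %% n
      if (k > 0) out <- segment[, c((n - k + 1):n, seq_len(n - k)), drop = FALSE]
    },
    time_stretch = {
      for (ch in seq_len(nrow(segment)))
        out[ch, ] <- .resampleKeepLength(segment[ch, ], spec$stretchFactor)
    },
    pitch_scale = {
      factor <- 2^(spec$semitones / 12)
      for (ch in seq_len(nrow(segment)))
        out[ch, ] <- .resampleKeepLength(segment[ch, ], factor)
    },
    random_gain = { out <- segment * 10^(spec$gainDb / 20) })
  out
}

#' Augment the training partition of a segment set
#'
#' Appends transformed copies of the selected segments.  Hard-fails on
#' any partition other than `"train"`: validation and test data must
#' never be augmented (leakage guard).
#'
#' @param segmentSet a [SegmentSet-class].
#' @param specs list of [augmentSpec()] objects, applied in turn to every
#'   segment matching `classes`.
#' @param partition partition tag of this segment set; only `"train"` is
#'   accepted.
#' @param classes segment labels eligible for augmentation.
#' @return the enlarged [SegmentSet-class].
#' @export
augmentSegments <- function(segmentSet, specs, partition = "train",
                            classes = c("seizure", "non-seizure")) {
  stopifnot(is(segmentSet, "SegmentSet"))
  if (!identical(partition, "train"))
    stop("augmentation refused: partition '", partition,
         "' must remain unaugmented (leakage guard)")
  keep <- which(segmentSet@labels %in% classes)
  segs <- segmentSet@segments
  labels <- segmentSet@labels
  lobes <- segmentSet@lobes
  starts <- segmentSet@starts
  for (sp in specs) {
    for (i in keep) {
      segs[[length(segs) + 1L]] <- augmentSignal(segmentSet@segments[[i]], sp)
      labels <- c(labels, segmentSet@labels[i])
      lobes <- c(lobes, segmentSet@lobes[i])
      starts <- c(starts, segmentSet@starts[i])
    }
  }
  initialize(segmentSet, segments = segs, labels = labels, lobes = lobes,
             starts = as.integer(starts))
}

# Magnitude STFT of one channel: rows = FFT bins, cols = frames.
.stft <- function(x, windowSamples, fftLength, hop) {
  n <- length(x)
  nFrames <- floor((n - windowSamples) / hop) + 1
  win <- signal::hamming(windowSamples)
  out <- matrix(0, fftLength %/% 2 + 1, nFrames)
  for (f in seq_len(nFrames)) {
    seg <- x[((f - 1) * hop + 1):((f - 1) * hop + windowSamples)] * win
    if (fftLength > windowSamples) seg <- c(seg, numeric(fftLength - windowSamples))
    sp <- fft(seg)
    out[, f] <- Mod(sp[seq_len(fftLength %/% 2 + 1)])
  }
  out
}

#' Averaged-channel STFT spectrogram of a segment
#'
#' Computes the magnitude STFT per channel (Hamming window of
#' `windowSamples`, FFT length `fftLength`, hop `hop`), crops to
#' `freqRange`, averages across channels, log-scales
#' (`log(x + epsilon)`), min-max normalizes to `[0, 1]` and resizes
#' bilinearly to `outSize`.
#'
#' @param segment channels x samples matrix (>= `windowSamples` columns).
#' @param samplingRate sampling rate in Hz.
#' @param windowSamples,fftLength,hop STFT parameters
#'   (defaults 256 / 256 / 128).
#' @param freqRange retained frequency band in Hz (default `c(0, 30)`).
#' @param outSize output image size (default `c(224, 224)`).
#' @param raw if `TRUE`, return the cropped channel-averaged magnitude
#'   matrix before log/normalize/resize (used by the frequency-bin
#'   diagnostics).
#' @return `outSize` matrix in `[0, 1]` with attribute `"stftParams"`,
#'   or the raw bins x frames matrix when `raw = TRUE`.
#' @export
eegSpectrogram <- function(segment, samplingRate = 256,
                           windowSamples = 256L, fftLength = 256L,
                           hop = 128L, freqRange = c(0, 30),
                           outSize = c(224L, 224L), raw = FALSE) {
  stopifnot(is.matrix(segment))
  if (ncol(segment) < windowSamples)
    stop("segment too short for the STFT window (", windowSamples, " samples)")
  freqs <- (seq_len(fftLength %/% 2 + 1) - 1) * samplingRate / fftLength
  keep <- freqs >= freqRange[1] & freqs <= freqRange[2]
  acc <- NULL
  for (ch in seq_len(nrow(segment))) {
    s <- .stft(segment[ch, ], windowSamples, fftLength, hop)[keep, , drop = FALSE]
    acc <- if (is.null(acc)) s else acc + s
  }
  avg <- acc / nrow(segment)
  if (raw) return(avg)
  lg <- log(avg + 1e-10)
  rng <- range(lg)
  norm <- if (diff(rng) < .Machine$double.eps) {
    matrix(0, nrow(lg), ncol(lg))
  } else (lg - rng[1]) / diff(rng)
  img <- EBImage::resize(norm, w = outSize[1], h = outSize[2])
  img <- pmin(pmax(img, 0), 1)
  attr(img, "stftParams") <- list(windowSamples = windowSamples,
                                  fftLength = fftLength, hop = hop,
                                  freqRange = freqRange)
  img
}
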