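# Recording-level preprocessing: zero-phase low-pass filtering, DT-CWT
# denoising applied per channel, sliding-window segmentation, electrode
# prefix -> lobe mapping, and annotation-driven segment labeling.

#' Zero-phase low-pass filter a recording
#'
#' 4th-order Butterworth applied forward and backward
#' (`signal::filtfilt`) per channel, so the passband is phase-neutral and
#' the length is preserved.
#'
#' @param recording an [EEGRecording-class].
#' @param cutoff cutoff frequency in Hz (default 30); must be below the
#'   Nyquist frequency.
#' @return the filtered [EEGRecording-class].
#' @export
lowpassFilter <- function(recording, cutoff = 30) {
  stopifnot(is(recording, "EEGRecording"))
  fs <- samplingRate(recording)
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  dat <- eegData(recording)
  n <- ncol(dat)
  # odd-reflection padding absorbs the zero-initial-condition transient
  p <- min(256L, n - 1L)
  for (ch in seq_len(nrow(dat))) {
    x <- dat[ch, ]
    xt <- c(2 * x[1] - rev(x[2:(p + 1)]), x,
            2 * x[n] - rev(x[(n - p):(n - 1)]))
    dat[ch, ] <- signal::filtfilt(bf, xt)[(p + 1):(p + n)]
  }
  initialize(recording, data = dat)
}

#' DT-CWT denoise every channel of a recording
#'
#' Applies [dtcwtDenoise()] channel by channel.
#'
#' @inheritParams lowpassFilter
#' @param levels decomposition depth.
#' @param threshold threshold rule, see [dtcwtDenoise()].
#' @return the denoised [EEGRecording-class].
#' @export
denoiseRecording <- function(recording, levels = 4L, threshold = "universal") {
  stopifnot(is(recording, "EEGRecording"))
  dat <- eegData(recording)
  for (ch in seq_len(nrow(dat)))
    dat[ch, ] <- dtcwtDenoise(dat[ch, ], levels, threshold)
  initialize(recording, data = dat)
}

#' Segment a recording into overlapping windows
#'
#' Sliding windows of `windowSec` seconds with hop
#' `(1 - overlap) * window`; 0-based half-open sample intervals
#' `[start, start + w)`; a trailing partial window is dropped.  The
#' window count equals `floor((N - w) / h) + 1`.  A recording shorter
#' than one window yields an empty set with a warning.
#'
#' @param recording an [EEGRecording-class].
#' @param windowSec window length in seconds (default 2).
#' @param overlap overlap fraction in `[0, 1)` (default 0.5).
#' @return a [SegmentSet-class] with labels `"unlabeled"`.
#' @export
segmentWindows <- function(recording, windowSec = 2.0, overlap = 0.5) {
  stopifnot(is(recording, "EEGRecording"), overlap >= 0, overlap < 1)
  fs <- samplingRate(recording)
  w <- round(windowSec * fs)
  h <- max(1L, round((1 - overlap) * w))
  n <- ncol(eegData(recording))
  if (n < w) {
    warning("recording shorter than one window; returning empty SegmentSet")
    starts <- integer(0)
  } else {
    starts <- seq.int(0L, n - w, by = h)
  }
  dat <- eegData(recording)
  segs <- lapply(starts, function(s) dat[, (s + 1L):(s + w), drop = FALSE])
  new("SegmentSet", segments = segs, windowSec = windowSec, overlap = overlap,
      samplingRate = fs,
      labels = rep("unlabeled", length(segs)),
      lobes = rep(NA_character_, length(segs)),
      starts = as.integer(starts), subject = "unknown",
      channelNames = channelNames(recording))
}

#' Map a 10-20 channel name to a cerebral lobe
#'
#' Uses the prefix of the FIRST electrode of a (possibly bipolar) channel
#' name: `FP`/`F` -> frontal, `T` -> temporal, `P` -> parietal,
#' `O` -> occipital.  Central (`C`) electrodes and unrecognized prefixes
#' map to `"excluded"`; the function never throws.
#'
#' @param name channel name, e.g. `"F7-T7"`.
#' @return one of `"frontal"`, `"temporal"`, `"parietal"`, `"occipital"`,
#'   `"excluded"`.
#' @export
#' @examples
#' mapChannelToLobe("F7-T7")   # frontal
#' mapChannelToLobe("C3-P3")   # excluded
mapChannelToLobe <- function(name) {
  first <- toupper(sub("-.*$", "", trimws(name)))
  prefix <- sub("[0-9Zz].*$", "", first)
  switch(prefix,
         "FP" = "frontal", "F" = "frontal",
         "T" = "temporal",
         "P" = "parietal",
         "O" = "occipital",
         "excluded")
}

#' Label segments from seizure annotations
#'
#' A segment is `"seizure"` when at least `seizureOverlap` of its samples
#' fall inside any annotated seizure interval; `"non-seizure"` when it
#' lies wholly outside every interval padded by `exclusionMarginSec`
#' (the inter-ictal exclusion margin); otherwise `"excluded"`.  Seizure
#' segments inherit the lobe of the annotation covering them.  The
#' labeling is total: every segment receives exactly one label.
#'
#' @param segmentSet a [SegmentSet-class].
#' @param annotations data.frame with `onset`, `offset` (seconds),
#'   `label` and optionally `lobe`.
#' @param exclusionMarginSec margin in seconds around seizures within
#'   which non-seizure windows are excluded (default 60).
#' @param seizureOverlap minimum in-seizure sample fraction for the
#'   seizure label (default 0.5).
#' @return the relabeled [SegmentSet-class].
#' @export
labelSegments <- function(segmentSet, annotations,
                          exclusionMarginSec = 60, seizureOverlap = 0.5) {
  stopifnot(is(segmentSet, "SegmentSet"))
  fs <- segmentSet@samplingRate
  w <- round(segmentSet@windowSec * fs)
  sz <- annotations[annotations$label == "seizure", , drop = FALSE]
  labels <- segmentSet@labels
  lobes <- segmentSet@lobes
  for (i in seq_along(segmentSet@segments)) {
    s0 <- segmentSet@starts[i]
    s1 <- s0 + w
    if (!nrow(sz)) {
      labels[i] <- "non-seizure"
      lobes[i] <- NA_character_
      next
    }
    a0 <- sz$onset * fs
    a1 <- sz$offset * fs
    inside <- pmax(0, pmin(s1, a1) - pmax(s0, a0))
    frac <- inside / w
    if (max(frac) >= seizureOverlap) {
      labels[i] <- "seizure"
      lobes[i] <- if ("lobe" %in% names(sz)) sz$lobe[which.max(frac)]
                  else NA_character_
    } else {
      m0 <- a0 - exclusionMarginSec * fs
      m1 <- a1 + exclusionMarginSec * fs
      touches <- any(pmin(s1, m1) - pmax(s0, m0) > 0)
      labels[i] <- if (touches) "excluded" else "non-seizure"
      lobes[i] <- NA_character_
    }
  }
  initialize(segmentSet, labels = labels, lobes = lobes)
}
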