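# Synthetic multichannel EEG with lobe-localized spike-wave seizures.
#
# Background = 1/f ("pink") noise plus narrowband alpha (8-13 Hz) and
# delta (0.5-4 Hz) oscillations with configurable relative powers.
# Seizures are ~3 Hz spike-wave bursts (biphasic Gaussian-derivative
# spike followed by a slow half-wave, the clinical archetype) injected
# only into the channels of one chosen lobe, with amplitude tiers
# Low/Medium/High.  Everything is deterministic under the config seed.

# Evaluate expr under a temporary RNG seed, restoring the caller's state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

.DEFAULT_CHANNELS <- c("FP1-F7", "F7-T7", "T7-P7", "P7-O1",
                       "O1-O2", "FP2-F8", "T8-P8", "P8-O2")

.TIER_FACTORS <- c(Low = 1.0, Medium = 2.0, High = 3.5)

#' Configuration for the synthetic EEG generator
#'
#' @param samplingRate sampling rate in Hz (default 256).
#' @param channelNames 10-20-system bipolar channel names; the default
#'   eight CHB-MIT-style channels cover all four lobes under the
#'   first-electrode prefix rule of [mapChannelToLobe()].
#' @param duration recording length in seconds.
#' @param seizureEvents data.frame with columns `onset`, `offset`
#'   (seconds), `lobe` (frontal/temporal/parietal/occipital) and `level`
#'   (Low/Medium/High); may have zero rows.
#' @param backgroundAlphaPower,backgroundDeltaPower relative band-power
#'   weights of the alpha and delta oscillations.
#' @param noiseLevel relative amplitude of the pink-noise floor.
#' @param spikeAmplitude base amplitude of a Low-tier spike-wave burst,
#'   in units of background RMS; tiers scale it by 1.0 / 2.0 / 3.5.
#' @param nSubjects number of synthetic subjects for [generateDataset()].
#' @param seed integer seed; fully determines the output.
#' @return a list of class `"SynthConfig"`.
#' @export
synthConfig <- function(samplingRate = 256, channelNames = .DEFAULT_CHANNELS,
                        duration = 60,
                        seizureEvents = data.frame(onset = numeric(0),
                                                   offset = numeric(0),
                                                   lobe = character(0),
                                                   level = character(0)),
                        backgroundAlphaPower = 1.0,
                        backgroundDeltaPower = 1.0,
                        noiseLevel = 1.0,
                        spikeAmplitude = 3.0,
                        nSubjects = 1L,
                        seed = 1L) {
  if (duration <= 0 || samplingRate <= 0)
    stop("invalid config: duration and samplingRate must be positive")
  if (nrow(seizureEvents)) {
    if (any(seizureEvents$onset >= seizureEvents$offset) ||
        any(seizureEvents$offset > duration))
      stop("invalid config: events need onset < offset <= duration")
    lobes <- vapply(channelNames, mapChannelToLobe, "")
    for (lb in unique(seizureEvents$lobe))
      if (!any(lobes == lb))
        stop("invalid config: no channel maps to lobe '", lb, "'")
  }
  structure(list(samplingRate = samplingRate, channelNames = channelNames,
                 duration = duration, seizureEvents = seizureEvents,
                 backgroundAlphaPower = backgroundAlphaPower,
                 backgroundDeltaPower = backgroundDeltaPower,
                 noiseLevel = noiseLevel, spikeAmplitude = spikeAmplitude,
                 nSubjects = as.integer(nSubjects), seed = as.integer(seed)),
            class = "SynthConfig")
}

# Unit-RMS pink noise via 1/f spectral shaping.
.pinkNoise <- function(n) {
  w <- rnorm(n)
  sp <- fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)                  # symmetric frequency index
  sp <- sp / sqrt(f)
  x <- Re(fft(sp, inverse = TRUE)) / n
  x / max(sd(x), .Machine$double.eps)
}

# Unit-RMS narrowband oscillation: bandpass-filtered white noise.
.bandNoise <- function(n, fs, low, high) {
  bf <- signal::butter(2, c(low, high) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  x / max(sd(x), .Machine$double.eps)
}

#' Generate background EEG
#'
#' Produces a channels x samples recording of pink noise plus alpha-band
#' (8-13 Hz) and delta-band (0.5-4 Hz) oscillations with the configured
#' relative powers.  With all weights zero the recording is identically
#' zero.  Output is reproducible under the config seed.
#'
#' @param config a [synthConfig()] object.
#' @return an [EEGRecording-class] without annotations.
#' @export
generateBackground <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  n <- round(config$duration * config$samplingRate)
  if (n < 1) stop("invalid config: duration x samplingRate < 1 sample")
  nch <- length(config$channelNames)
  dat <- withSeed(config$seed, {
    m <- matrix(0, nch, n)
    for (ch in seq_len(nch)) {
      x <- numeric(n)
      if (config$noiseLevel > 0) x <- x + config$noiseLevel * .pinkNoise(n)
      if (config$backgroundAlphaPower > 0)
        x <- x + sqrt(config$backgroundAlphaPower) *
          .bandNoise(n, config$samplingRate, 8, 13)
      if (config$backgroundDeltaPower > 0)
        x <- x + sqrt(config$backgroundDeltaPower) *
          .bandNoise(n, config$samplingRate, 0.5, 4)
      m[ch, ] <- x
    }
    m
  })
  new("EEGRecording", data = dat, samplingRate = config$samplingRate,
      channelNames = config$channelNames)
}

# One ~3 Hz spike-wave cycle: biphasic spike (Gaussian derivative,
# sigma 12 ms) followed by a slow half-wave filling the cycle.
.spikeWaveCycle <- function(fs, rate = 3) {
  len <- round(fs / rate)
  t <- seq_len(len) / fs
  sigma <- 0.012
  tc <- 0.04
  spike <- -(t - tc) / sigma * exp(-((t - tc)^2) / (2 * sigma^2))
  spike <- spike / max(abs(spike))
  wave <- numeric(len)
  wi <- t > 0.09
  wave[wi] <- 0.6 * sin(pi * (t[wi] - 0.09) / (max(t) - 0.09))
  spike * 2 + wave
}

#' Inject a spike-wave seizure burst into one lobe
#'
#' Adds a ~3 Hz spike-wave burst to the channels mapped to `lobe`, with
#' amplitude `spikeAmplitude * tierFactor(level)` (tiers Low/Medium/High
#' scale by 1.0 / 2.0 / 3.5) and half-second cosine on/off ramps.
#' Channels of other lobes are untouched.  The event is appended to the
#' recording's annotations (also when `amplitude` is zero, so the label
#' mask stays truthful to the intended event).
#'
#' @param recording an [EEGRecording-class].
#' @param onset,offset event interval in seconds, inside the recording.
#' @param lobe target lobe (frontal/temporal/parietal/occipital).
#' @param level activity tier, one of `"Low"`, `"Medium"`, `"High"`.
#' @param amplitude base burst amplitude (default the generator's
#'   `spikeAmplitude`, 3.0); `0` leaves the signal unchanged.
#' @param seed seed for the burst's per-channel phase jitter.
#' @return the annotated [EEGRecording-class].
#' @export
injectSeizure <- function(recording, onset, offset, lobe,
                          level = c("Medium", "Low", "High"),
                          amplitude = 3.0, seed = 1L) {
  stopifnot(is(recording, "EEGRecording"))
  level <- match.arg(level)
  fs <- samplingRate(recording)
  n <- ncol(eegData(recording))
  if (onset < 0 || offset <= onset || offset * fs > n + 1e-9)
    stop("event interval must lie inside the recording")
  lobes <- vapply(channelNames(recording), mapChannelToLobe, "")
  chans <- which(lobes == lobe)
  if (!length(chans)) stop("no channel maps to lobe '", lobe, "'")

  i0 <- floor(onset * fs) + 1L
  i1 <- min(ceiling(offset * fs), n)
  len <- i1 - i0 + 1L
  amp <- amplitude * .TIER_FACTORS[[level]]
  dat <- eegData(recording)
  if (amp > 0 && len > 1) {
    cyc <- .spikeWaveCycle(fs)
    ramp <- pmin(1, pmin(seq_len(len), rev(seq_len(len))) / (0.5 * fs))
    jit <- withSeed(seed, sample.int(length(cyc), length(chans), replace = TRUE) - 1L)
    for (k in seq_along(chans)) {
      rolled <- if (jit[k] == 0) cyc else c(cyc[-seq_len(jit[k])], cyc[seq_len(jit[k])])
      dat[chans[k], i0:i1] <- dat[chans[k], i0:i1] + rep_len(rolled, len) * ramp * amp
    }
  }
  ann <- annotations(recording)
  newRow <- data.frame(onset = onset, offset = offset, label = "seizure",
                       lobe = lobe, level = level, stringsAsFactors = FALSE)
  if (!"lobe" %in% names(ann) && nrow(ann)) {
    ann$lobe <- NA_character_
    ann$level <- NA_character_
  }
  ann <- if (nrow(ann)) rbind(ann, newRow) else newRow
  new("EEGRecording", data = dat, samplingRate = fs,
      channelNames = channelNames(recording), annotations = ann)
}

#' Per-sample seizure mask of a recording
#'
#' @param recording an annotated [EEGRecording-class].
#' @return logical vector, one entry per sample, `TRUE` exactly inside
#'   annotated seizure intervals.
#' @export
seizureMask <- function(recording) {
  fs <- samplingRate(recording)
  n <- ncol(eegData(recording))
  mask <- logical(n)
  ann <- annotations(recording)
  sz <- ann[ann$label == "seizure", , drop = FALSE]
  for (i in seq_len(nrow(sz))) {
    i0 <- floor(sz$onset[i] * fs) + 1L
    i1 <- min(ceiling(sz$offset[i] * fs), n)
    mask[i0:i1] <- TRUE
  }
  mask
}

#' Plan a seizure interval yielding a requested number of seizure windows
#'
#' Searches (over hop-aligned interval lengths) for the event interval
#' starting at `onset` for which [labelSegments()]'s majority rule marks
#' exactly `nSegments` windows as seizure, so datasets can hit a
#' requested class balance within one segment.
#'
#' @param nSegments requested seizure-labeled window count (>= 1).
#' @param duration recording duration (s).
#' @param onset event start (s).
#' @param windowSec,overlap,samplingRate segmentation parameters.
#' @return c(onset, offset) in seconds.
#' @export
planSeizureEvent <- function(nSegments, duration, onset = 10,
                             windowSec = 2, overlap = 0.5,
                             samplingRate = 256) {
  w <- round(windowSec * samplingRate)
  h <- round((1 - overlap) * w)
  n <- round(duration * samplingRate)
  starts <- seq.int(0L, n - w, by = h)
  countFor <- function(offset) {
    s0 <- onset * samplingRate
    s1 <- offset * samplingRate
    inside <- pmax(0, pmin(starts + w, s1) - pmax(starts, s0))
    sum(inside >= w / 2)
  }
  for (offset in seq(onset + windowSec / 2, duration, by = h / samplingRate)) {
    if (countFor(offset) >= nSegments) return(c(onset, offset))
  }
  stop("recording too short for the requested seizure segment count")
}

#' Generate a subject-wise split synthetic dataset
#'
#' Creates `config$nSubjects` independent synthetic recordings (each with
#' its own derived seed and the configured seizure events; lobes and
#' activity levels rotate across subjects when `seizureEvents` has a
#' `rotate` attribute or via the default two events per subject), then
#' partitions the *subjects* 70/10/20 into train/validation/test (each
#' partition receives at least one subject; no subject appears twice).
#'
#' @param config a [synthConfig()]; `nSubjects >= 3`.
#' @param eventsPerSubject number of seizure events per subject when
#'   `config$seizureEvents` is empty (default 2); events are placed at
#'   deterministic offsets with rotating lobe and level.
#' @return list with elements `train`, `validation`, `test` (lists of
#'   annotated [EEGRecording-class] objects, names = subject ids) and
#'   `subjects` (the per-partition subject ids).
#' @export
generateDataset <- function(config, eventsPerSubject = 2L) {
  stopifnot(inherits(config, "SynthConfig"))
  ns <- config$nSubjects
  if (ns < 3L) stop("need at least 3 subjects for a 3-way subject split")
  lobeCycle <- c("frontal", "temporal", "parietal", "occipital")
  levelCycle <- c("Low", "Medium", "High")
  recs <- vector("list", ns)
  evCounter <- 0L
  for (s in seq_len(ns)) {
    cfg <- config
    cfg$seed <- config$seed + 1000L * s
    rec <- generateBackground(cfg)
    events <- config$seizureEvents
    if (!nrow(events)) {
      slots <- seq(0.2, 0.75, length.out = eventsPerSubject) * config$duration
      evLen <- min(12, 0.12 * config$duration)
      events <- do.call(rbind, lapply(seq_len(eventsPerSubject), function(e) {
        evCounter <<- evCounter + 1L
        data.frame(onset = slots[e], offset = slots[e] + evLen,
                   lobe = lobeCycle[(evCounter - 1L) %% 4L + 1L],
                   level = levelCycle[(evCounter - 1L) %% 3L + 1L],
                   stringsAsFactors = FALSE)
      }))
    }
    for (i in seq_len(nrow(events)))
      rec <- injectSeizure(rec, events$onset[i], events$offset[i],
                           events$lobe[i], events$level[i],
                           amplitude = config$spikeAmplitude,
                           seed = cfg$seed + i)
    recs[[s]] <- rec
  }
  names(recs) <- sprintf("subj%02d", seq_len(ns))

  nVal <- max(1L, round(0.1 * ns))
  nTest <- max(1L, round(0.2 * ns))
  nTrain <- ns - nVal - nTest
  if (nTrain < 1L) stop("fewer subjects than partitions")
  ids <- names(recs)
  list(train = recs[ids[seq_len(nTrain)]],
       validation = recs[ids[nTrain + seq_len(nVal)]],
       test = recs[ids[(nTrain + nVal + 1L):ns]],
       subjects = list(train = ids[seq_len(nTrain)],
                       validation = ids[nTrain + seq_len(nVal)],
                       test = ids[(nTrain + nVal + 1L):ns]))
}

#' Write a synthetic dataset to EDF files
#'
#' One EDF per subject plus a tab-separated annotation companion file,
#' mirroring the layout of clinical EDF corpora.
#'
#' @param dataset result of [generateDataset()].
#' @param dir output directory (created if missing).
#' @return character vector of written EDF paths, invisibly.
#' @export
writeDatasetEDF <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (part in c("train", "validation", "test")) {
    for (id in names(dataset[[part]])) {
      p <- file.path(dir, paste0(id, ".edf"))
      writeEDF(dataset[[part]][[id]], p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
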