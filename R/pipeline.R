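# End-to-end orchestration: synthesis/ingestion -> preprocessing ->
# augmentation (train only) -> spectrograms -> backbone features ->
# wrapper feature selection -> detection -> fuzzy activity index ->
# lobe localization -> metrics.

#' Pipeline configuration
#'
#' Defaults define the package's desk-scale synthetic benchmark:
#' 10 subjects x 180 s x 8 channels at 256 Hz, two 12-s seizure events
#' per subject with rotating lobes and activity tiers, a 64 x 64
#' spectrogram and a 1/8-width backbone.
#'
#' @param nSubjects synthetic subjects (>= 3).
#' @param duration per-subject recording length (s).
#' @param samplingRate Hz.
#' @param spikeAmplitude base burst amplitude (background-RMS units).
#' @param eventsPerSubject seizure events per subject.
#' @param denoise apply DT-CWT denoising (default TRUE).
#' @param lowpassCutoff low-pass cutoff (Hz).
#' @param windowSec,overlap segmentation parameters.
#' @param exclusionMarginSec inter-ictal exclusion margin (s); the
#'   benchmark uses 15 s so that 180-s records retain non-seizure
#'   segments.
#' @param augmentPartitions partitions to augment; anything but
#'   `"train"` triggers the leakage guard.
#' @param spectrogramSize spectrogram image size.
#' @param backboneScale backbone width scale.
#' @param backboneEpochs backbone training epochs (benchmark <= 10).
#' @param backboneBlocks bottleneck blocks per stage of the scaled
#'   topology (depth-reduced relative to the reference `c(3, 4, 6, 3)`).
#' @param backboneTrainMax max training spectrograms for the backbone
#'   epochs (subsampled, seeded).
#' @param backboneBatch,backboneLr backbone minibatch size and Adam
#'   learning rate.
#' @param hbo an [hboConfig()] for the deep-feature selection (scaled
#'   down relative to the reference 30 x 100 search).
#' @param owgru an [owgruConfig()] for the localizer.
#' @param owgruEpochs localizer training epochs.
#' @param tuneTrials localizer tuning trials (0 = use defaults, skip
#'   tuning).
#' @param seed master seed; every stage derives its stream from it.
#' @return a list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(nSubjects = 10L, duration = 120, samplingRate = 256,
                           spikeAmplitude = 3.0, eventsPerSubject = 2L,
                           denoise = TRUE, lowpassCutoff = 30,
                           windowSec = 2, overlap = 0.5,
                           exclusionMarginSec = 15,
                           augmentPartitions = "train",
                           spectrogramSize = c(64L, 64L),
                           backboneScale = 0.125, backboneEpochs = 3L,
                           backboneBlocks = c(1L, 1L, 1L, 1L),
                           backboneTrainMax = 384L,
                           backboneBatch = 32L, backboneLr = 1e-4,
                           hbo = hboConfig(nPop = 12L, iterations = 15L,
                                           seed = 1L),
                           owgru = owgruConfig(seed = 1L),
                           owgruEpochs = 60L, tuneTrials = 0L,
                           seed = 1L) {
  structure(as.list(environment()), class = "PipelineConfig")
}

.segmentsToSpectrograms <- function(segs, fs, size) {
  lapply(segs, eegSpectrogram, samplingRate = fs, outSize = size)
}

# Preprocess one partition: filter, (denoise), segment, label.
.preprocessPartition <- function(recs, cfg) {
  out <- list()
  for (id in names(recs)) {
    rec <- lowpassFilter(recs[[id]], cfg$lowpassCutoff)
    if (cfg$denoise) rec <- denoiseRecording(rec)
    ss <- segmentWindows(rec, cfg$windowSec, cfg$overlap)
    ss <- labelSegments(ss, annotations(recs[[id]]), cfg$exclusionMarginSec)
    ss@subject <- id
    out[[id]] <- ss
  }
  out
}

.usable <- function(ss) which(ss@labels %in% c("seizure", "non-seizure"))

# Flatten per-subject segment sets into one pool.
.poolSegments <- function(ssList) {
  segs <- list(); labels <- character(0); lobes <- character(0)
  subjects <- character(0)
  for (ss in ssList) {
    idx <- .usable(ss)
    segs <- c(segs, ss@segments[idx])
    labels <- c(labels, ss@labels[idx])
    lobes <- c(lobes, ss@lobes[idx])
    subjects <- c(subjects, rep(ss@subject, length(idx)))
  }
  list(segments = segs, labels = labels, lobes = lobes, subjects = subjects)
}

# Balance classes in the training pool by augmenting the minority class.
.augmentBalance <- function(pool, cfg) {
  tab <- table(factor(pool$labels, levels = c("seizure", "non-seizure")))
  minority <- names(tab)[which.min(tab)]
  deficit <- abs(diff(as.numeric(tab)))
  if (deficit == 0L) return(pool)
  idx <- which(pool$labels == minority)
  transforms <- c("noise_injection", "polarity_inversion", "time_shift",
                  "random_gain", "time_stretch", "pitch_scale")
  k <- 0L
  while (deficit > 0L && k < 6L * length(idx)) {
    i <- idx[k %% length(idx) + 1L]
    sp <- augmentSpec(transforms[k %% length(transforms) + 1L],
                      targetSnrDb = 10, shiftSec = 0.12,
                      stretchFactor = 1.05, semitones = 1, gainDb = 3,
                      seed = cfg$seed + k)
    pool$segments[[length(pool$segments) + 1L]] <-
      augmentSignal(pool$segments[[i]], sp)
    pool$labels <- c(pool$labels, pool$labels[i])
    pool$lobes <- c(pool$lobes, pool$lobes[i])
    pool$subjects <- c(pool$subjects, pool$subjects[i])
    k <- k + 1L
    deficit <- deficit - 1L
  }
  pool
}

#' Run the full seizure-analysis pipeline on synthetic data
#'
#' Generates the synthetic dataset, preprocesses all partitions,
#' augments the training pool (leakage-guarded), computes spectrograms,
#' briefly trains the backbone and extracts deep features, selects
#' features with the honey-badger search, trains and evaluates the
#' detection head, fits the fuzzy activity index on training features,
#' trains the Wave-GRU localizer on training seizure segments, and
#' evaluates detection and localization on the held-out test subjects.
#'
#' @param config a [pipelineConfig()].
#' @param verbose print stage progress.
#' @return a list of class `"PipelineReport"`: detection metrics,
#'   localization metrics, selected features, activity-index summary,
#'   and a manifest (config, seeds, partition subjects, segment counts).
#' @export
runPipeline <- function(config = pipelineConfig(), verbose = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  for (p in config$augmentPartitions)
    if (!identical(p, "train"))
      stop("augmentation refused: partition '", p,
           "' must remain unaugmented (leakage guard)")

  say("[synth] generating %d subjects", config$nSubjects)
  scfg <- synthConfig(samplingRate = config$samplingRate,
                      duration = config$duration,
                      spikeAmplitude = config$spikeAmplitude,
                      nSubjects = config$nSubjects, seed = config$seed)
  ds <- generateDataset(scfg, config$eventsPerSubject)

  say("[preprocess] filter/denoise/segment/label")
  parts <- lapply(ds[c("train", "validation", "test")],
                  .preprocessPartition, cfg = config)
  pools <- lapply(parts, .poolSegments)
  if (length(pools$train$segments) == 0L || length(pools$test$segments) == 0L)
    stop("pipeline stage 'segment': no usable segments produced")

  say("[augment] balancing training classes")
  pools$train <- .augmentBalance(pools$train, config)

  say("[stft] %d spectrograms",
      sum(vapply(pools, function(p) length(p$segments), 1L)))
  specs <- lapply(pools, function(p)
    .segmentsToSpectrograms(p$segments, config$samplingRate,
                            config$spectrogramSize))

  say("[backbone] training %d epochs", config$backboneEpochs)
  # depth-reduced scaled topology; stem stride 2 and stage strides
  # (1,2,1,1) keep the inception head on 8x8 maps for 64x64 inputs
  bcfg <- backboneConfig(inputSize = config$spectrogramSize,
                         scale = config$backboneScale,
                         baseBlocks = config$backboneBlocks,
                         initialStride = 2L,
                         stageStrides = c(1L, 2L, 1L, 1L),
                         seed = config$seed)
  model <- buildBackbone(bcfg)
  yTrain <- factor(pools$train$labels, levels = c("non-seizure", "seizure"))
  nTr <- length(specs$train)
  sub <- withSeed(config$seed + 3L,
                  sample.int(nTr, min(config$backboneTrainMax, nTr)))
  if (config$backboneEpochs > 0L) {
    trainBackbone(model, specs$train[sub], as.integer(yTrain)[sub],
                  epochs = config$backboneEpochs,
                  batchSize = config$backboneBatch,
                  lr = config$backboneLr, seed = config$seed + 4L)
  }
  calibrateBackbone(model, specs$train[sub], passes = 2L,
                    batchSize = config$backboneBatch,
                    seed = config$seed + 8L)

  say("[features] extracting deep features")
  feats <- lapply(specs, function(s)
    extractFeatures(model, s, batchSize = config$backboneBatch))
  gc(verbose = FALSE)

  say("[select] honey-badger feature selection")
  sel <- hboSelect(feats$train, pools$train$labels, config$hbo)

  say("[detect] training the FC head (%d features)", length(sel$selected))
  det <- trainDetector(feats$train[, sel$selected, drop = FALSE],
                       yTrain, seed = config$seed + 5L)
  predTest <- predictDetector(det,
                              feats$test[, sel$selected, drop = FALSE])
  detCounts <- confusionCounts(predTest$class, pools$test$labels, "seizure")
  detMetrics <- suppressMessages(computeMetrics(detCounts))

  say("[befls] fitting fuzzy memberships")
  fuzzTrain <- t(vapply(pools$train$segments, segmentFuzzyFeatures,
                        numeric(3), samplingRate = config$samplingRate))
  rb <- fitMemberships(fuzzTrain)
  indexFor <- function(pool) {
    vapply(pool$segments, function(seg)
      inferIndex(segmentFuzzyFeatures(seg, config$samplingRate), rb)$DF,
      numeric(1))
  }
  dfTrain <- indexFor(pools$train)
  dfTest <- indexFor(pools$test)

  say("[localize] training the Wave-GRU")
  seqFor <- function(pool, dfs) {
    idx <- which(pool$labels == "seizure" & !is.na(pool$lobes))
    list(idx = idx,
         seqs = lapply(idx, function(i)
           cbind(lobeBandSequence(pool$segments[[i]],
                                  channelNames(ds$train[[1]]),
                                  config$samplingRate), dfs[i])),
         lobes = pool$lobes[idx])
  }
  trLoc <- seqFor(pools$train, dfTrain)
  teLoc <- seqFor(pools$test, dfTest)
  locCfg <- config$owgru
  locCfg$seed <- config$seed + 6L
  if (config$tuneTrials > 0L) {
    locCfg$trials <- config$tuneTrials
    tuned <- tuneOWGRU(trLoc$seqs, trLoc$lobes, locCfg)
    loc <- trainLocalizer(trLoc$seqs, trLoc$lobes, locCfg,
                          epochs = config$owgruEpochs,
                          lr = tuned$best$lr,
                          optimizer = tuned$best$optimizer %||% "adam")
  } else {
    tuned <- NULL
    loc <- trainLocalizer(trLoc$seqs, trLoc$lobes, locCfg,
                          epochs = config$owgruEpochs)
  }
  locProbs <- localize(loc, teLoc$seqs)
  locPred <- colnames(locProbs)[max.col(locProbs, ties.method = "first")]
  locMetrics <- multiclassMetrics(locPred, teLoc$lobes)

  report <- structure(list(
    detection = list(metrics = detMetrics, counts = detCounts,
                     nTest = length(pools$test$labels)),
    localization = list(accuracy = locMetrics$accuracy,
                        macro = locMetrics$macro,
                        perClass = locMetrics$perClass,
                        nTest = length(teLoc$lobes)),
    selection = list(selected = sel$selected,
                     bestFitness = sel$bestFitness,
                     trace = sel$trace),
    activityIndex = list(trainMeanDF = mean(dfTrain),
                         testMeanDF = mean(dfTest)),
    tuning = tuned,
    manifest = list(seed = config$seed, config = unclass(config),
                    subjects = ds$subjects,
                    segmentCounts = vapply(pools, function(p)
                      length(p$labels), 1L),
                    elapsedSec = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")))),
    class = "PipelineReport")
  report
}

#' @export
print.PipelineReport <- function(x, ...) {
  m <- x$detection$metrics
  cat("Pipeline report\n")
  cat(sprintf("  detection  (n=%d): AC %.3f | PR %.3f | RE %.3f | SP %.3f | F1 %.3f | MCC %.3f\n",
              x$detection$nTest, m["AC"], m["PR"], m["RE"], m["SP"],
              m["F1"], m["MCC"]))
  cat(sprintf("  localization (n=%d): accuracy %.3f\n",
              x$localization$nTest, x$localization$accuracy))
  cat(sprintf("  selected features: %d | best fitness %.3f\n",
              length(x$selection$selected), x$selection$bestFitness))
  cat(sprintf("  elapsed: %.1f s\n", x$manifest$elapsedSec))
  invisible(x)
}
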