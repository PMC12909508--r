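test_that("degenerate config with all weights zero yields an all-zero recording", {
  cfg <- synthConfig(duration = 4, noiseLevel = 0, backgroundAlphaPower = 0,
                     backgroundDeltaPower = 0, seed = 3)
  rec <- generateBackground(cfg)
  expect_true(all(eegData(rec) == 0))
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- synthConfig(duration = 6, seed = 42)
  r1 <- generateBackground(cfg)
  r2 <- generateBackground(cfg)
  expect_identical(eegData(r1), eegData(r2))
})

test_that("alpha-dominant config concentrates power in the alpha band", {
  cfg <- synthConfig(duration = 20, backgroundAlphaPower = 25,
                     backgroundDeltaPower = 0.1, noiseLevel = 0.1, seed = 7)
  x <- eegData(generateBackground(cfg))[1, ]
  expect_gt(oracleBandPower(x, 256, 8, 13), oracleBandPower(x, 256, 0.5, 4))
})

test_that("invalid configs are rejected", {
  expect_error(synthConfig(duration = 0), "invalid config")
  expect_error(synthConfig(duration = 10,
                           seizureEvents = data.frame(onset = 5, offset = 3,
                                                      lobe = "frontal",
                                                      level = "Low")),
               "onset < offset")
  expect_error(synthConfig(duration = 10, channelNames = c("FP1-F7", "C3-C4"),
                           seizureEvents = data.frame(onset = 1, offset = 3,
                                                      lobe = "occipital",
                                                      level = "Low")),
               "no channel maps")
})

test_that("seizure injection raises RMS only on the target lobe", {
  cfg <- synthConfig(duration = 30, seed = 11)
  rec <- generateBackground(cfg)
  rec2 <- injectSeizure(rec, 10, 18, "frontal", "Medium", seed = 12)
  idx <- (10 * 256 + 1):(18 * 256)
  lobes <- vapply(channelNames(rec), mapChannelToLobe, "")
  for (lb in c("frontal", "temporal", "parietal", "occipital")) {
    ch <- which(lobes == lb)
    r0 <- sqrt(mean(eegData(rec)[ch, idx]^2))
    r1 <- sqrt(mean(eegData(rec2)[ch, idx]^2))
    if (lb == "frontal") expect_gt(r1 / r0, 1.5)
    else expect_lt(abs(r1 / r0 - 1), 0.01)
  }
})

test_that("High-tier bursts have strictly greater in-burst RMS than Low", {
  cfg <- synthConfig(duration = 30, seed = 21)
  rec <- generateBackground(cfg)
  idx <- (10 * 256 + 1):(18 * 256)
  ch <- which(vapply(channelNames(rec), mapChannelToLobe, "") == "parietal")
  rmsFor <- function(level) {
    r <- injectSeizure(rec, 10, 18, "parietal", level, seed = 5)
    sqrt(mean(eegData(r)[ch, idx]^2))
  }
  expect_gt(rmsFor("High"), rmsFor("Low"))
})

test_that("zero-amplitude injection leaves the signal unchanged but sets the mask", {
  rec <- generateBackground(synthConfig(duration = 20, seed = 31))
  rec2 <- injectSeizure(rec, 5, 9, "temporal", "High", amplitude = 0)
  expect_identical(eegData(rec2), eegData(rec))
  m <- seizureMask(rec2)
  expect_true(all(m[(5 * 256 + 1):(9 * 256)]))
  expect_false(any(m[1:(5 * 256)]))
})

test_that("injection outside the recording or into an unmapped lobe errors", {
  rec <- generateBackground(synthConfig(duration = 10, seed = 1))
  expect_error(injectSeizure(rec, 8, 12, "frontal"), "inside the recording")
  recNoOcc <- new("EEGRecording",
                  data = eegData(rec)[1:2, , drop = FALSE],
                  samplingRate = 256, channelNames = c("FP1-F7", "F7-T7"))
  expect_error(injectSeizure(recNoOcc, 2, 5, "occipital"), "no channel maps")
})

test_that("subject-wise split is 70/10/20 with at least one subject each", {
  ds10 <- generateDataset(synthConfig(duration = 40, nSubjects = 10, seed = 2))
  expect_length(ds10$subjects$train, 7)
  expect_length(ds10$subjects$validation, 1)
  expect_length(ds10$subjects$test, 2)
  ds3 <- generateDataset(synthConfig(duration = 40, nSubjects = 3, seed = 2))
  expect_equal(lengths(ds3$subjects), c(train = 1L, validation = 1L, test = 1L))
  expect_error(generateDataset(synthConfig(duration = 40, nSubjects = 2)),
               "at least 3 subjects")
})

test_that("partitions are subject-disjoint and the dataset is seed-deterministic", {
  cfg <- synthConfig(duration = 40, nSubjects = 6, seed = 9)
  ds <- generateDataset(cfg)
  ids <- ds$subjects
  expect_length(intersect(ids$train, ids$validation), 0)
  expect_length(intersect(ids$train, ids$test), 0)
  expect_length(intersect(ids$validation, ids$test), 0)
  ds2 <- generateDataset(cfg)
  expect_identical(lapply(ds$train, eegData), lapply(ds2$train, eegData))
})

test_that("planned seizure events hit the requested window count within one", {
  for (k in c(3, 7, 12)) {
    ev <- planSeizureEvent(k, duration = 120, onset = 20)
    rec <- makeTinyRecording(seed = k, duration = 120, onset = ev[1],
                             offset = ev[2])
    ss <- labelSegments(segmentWindows(rec), annotations(rec))
    expect_lte(abs(sum(segmentLabels(ss) == "seizure") - k), 1)
  }
})

test_that("in-burst low-frequency power identifies the labeled lobe", {
  ds <- generateDataset(synthConfig(duration = 60, nSubjects = 3, seed = 17))
  for (rec in c(ds$train, ds$test)) {
    ann <- annotations(rec)
    lobes <- vapply(channelNames(rec), mapChannelToLobe, "")
    for (i in seq_len(nrow(ann))) {
      idx <- (round(ann$onset[i] * 256) + 1):(round(ann$offset[i] * 256))
      pw <- apply(eegData(rec)[, idx], 1, oracleBandPower, 256, 2, 4)
      perLobe <- tapply(pw, lobes, mean)
      expect_identical(names(which.max(perLobe)), ann$lobe[i])
    }
  }
})

test_that("EDF round trip preserves signal, names, rate and annotations", {
  rec <- makeTinyRecording(seed = 5)
  p <- withr::local_tempfile(fileext = ".edf")
  writeEDF(rec, p)
  back <- readEDF(p)
  # 16-bit quantization: error bounded by one physical quantum
  quantum <- max(abs(eegData(rec))) / 32767
  expect_lt(max(abs(eegData(back) - eegData(rec))), 2 * quantum)
  expect_identical(channelNames(back), channelNames(rec))
  expect_equal(samplingRate(back), 256)
  expect_equal(annotations(back)$onset, annotations(rec)$onset)
  expect_identical(annotations(back)$lobe, annotations(rec)$lobe)
})

test_that("malformed EDF headers are rejected", {
  p <- withr::local_tempfile(fileext = ".edf")
  writeLines("this is not an EDF file", p)
  expect_error(readEDF(p))
  # valid file, then declare zero channels in the header
  rec <- generateBackground(synthConfig(duration = 5, seed = 6))
  p2 <- withr::local_tempfile(fileext = ".edf")
  writeEDF(rec, p2)
  con <- file(p2, "r+b")
  seek(con, 252, rw = "write")
  writeChar("0   ", con, eos = NULL)
  close(con)
  expect_error(readEDF(p2), "0 channels")
})

test_that("annotations outside the record duration fail validation on read", {
  rec <- makeTinyRecording(seed = 7, duration = 10, onset = 2, offset = 5)
  p <- withr::local_tempfile(fileext = ".edf")
  writeEDF(rec, p)
  ann <- utils::read.table(paste0(p, ".annotations.txt"), header = TRUE,
                           sep = "\t")
  ann$offset <- 99
  utils::write.table(ann, paste0(p, ".annotations.txt"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(readEDF(p), "outside record duration")
})

test_that("writeDatasetEDF writes one EDF plus annotations per subject", {
  ds <- generateDataset(synthConfig(duration = 20, nSubjects = 3, seed = 3))
  dir <- withr::local_tempdir()
  paths <- writeDatasetEDF(ds, dir)
  expect_length(paths, 3)
  expect_true(all(file.exists(paths)))
  expect_true(all(file.exists(paste0(paths, ".annotations.txt"))))
})
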