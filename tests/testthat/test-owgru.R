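iw <- asNamespace("ictalwave")

test_that("the wave activation is elementwise sine with range [-1, 1]", {
  expect_identical(waveActivation(0), 0)
  expect_equal(waveActivation(pi / 2), 1)
  set.seed(1)
  x <- rnorm(1000, sd = 10)
  expect_true(all(abs(waveActivation(x)) <= 1))
  expect_equal(waveActivation(x), sin(x))
})

test_that("zero weights give 0.5 gates and a zero candidate", {
  p <- iw$.mkGRULayer(3L, 4L)
  for (nm in c("Kr", "Ku", "Kc")) p[[nm]]$val[] <- 0
  r <- owgruStep(rnorm(3), rnorm(4), p)
  expect_equal(unname(r$r[1, ]), rep(0.5, 4))
  expect_equal(unname(r$u[1, ]), rep(0.5, 4))
  expect_equal(unname(r$cand[1, ]), rep(0, 4))
})

test_that("a forced-closed mixing gate freezes the hidden state", {
  set.seed(2)
  p <- iw$.mkGRULayer(3L, 4L)
  h0 <- matrix(rnorm(4), 1)
  p$bu$val[] <- -100                      # update gate -> 0 (default mode)
  r <- owgruStep(matrix(rnorm(3), 1), h0, p)
  expect_equal(r$h, h0, tolerance = 1e-12)
  p2 <- iw$.mkGRULayer(3L, 4L)
  p2$br$val[] <- -100                     # reset gate -> 0 (literal mode)
  r2 <- owgruStep(matrix(rnorm(3), 1), h0, p2, literal = TRUE)
  expect_equal(r2$h, h0, tolerance = 1e-12)
})

test_that("gate and candidate ranges hold over random draws in both modes", {
  set.seed(3)
  for (i in 1:100) {
    p <- iw$.mkGRULayer(5L, 6L)
    x <- matrix(rnorm(10, sd = 3), 2)
    h <- matrix(rnorm(12, sd = 3), 2)
    for (literal in c(FALSE, TRUE)) {
      r <- owgruStep(x, h, p, literal)
      expect_true(all(r$r > 0 & r$r < 1))
      expect_true(all(r$u > 0 & r$u < 1))
      expect_true(all(abs(r$cand) <= 1))
      lo <- pmin(h, r$cand)
      hi <- pmax(h, r$cand)
      expect_true(all(r$h >= lo - 1e-12 & r$h <= hi + 1e-12))
    }
  }
})

test_that("default and literal gate modes differ measurably", {
  set.seed(4)
  p <- iw$.mkGRULayer(5L, 6L)
  x <- matrix(rnorm(5), 1)
  h <- matrix(rnorm(6), 1)
  expect_gt(max(abs(owgruStep(x, h, p)$h - owgruStep(x, h, p, TRUE)$h)), 1e-8)
})

test_that("gradients survive 100 time steps through the sine candidate", {
  for (s in 1:10)
    expect_gt(owgruGradientProbe(T = 100L, seed = s), 1e-8)
})

test_that("localization probabilities sum to 1 and are deterministic in eval mode", {
  cfg <- owgruConfig(layers = 2L, units = 8L, seed = 5)
  m <- buildOWGRU(4L, 4L, cfg)
  set.seed(6)
  seqs <- lapply(1:3, function(i) matrix(rnorm(8 * 3), 8, 3))
  p1 <- localize(m, seqs, fuzzyIndex = c(0.2, 0.5, 0.8))
  expect_equal(unname(rowSums(p1)), rep(1, 3), tolerance = 1e-6)
  p2 <- localize(m, seqs, fuzzyIndex = c(0.2, 0.5, 0.8))
  expect_identical(p1, p2)
  expect_identical(colnames(p1),
                   c("frontal", "temporal", "parietal", "occipital"))
  expect_error(localize(m, matrix(0, 0, 4)), "empty sequence")
})

test_that("training separates strongly lobe-coded sequences", {
  set.seed(7)
  lobes <- c("frontal", "temporal", "parietal", "occipital")
  mkSeq <- function(lobe) {
    m <- matrix(rnorm(8 * 4, sd = 0.2), 8, 4)
    m[, match(lobe, lobes)] <- m[, match(lobe, lobes)] + 2
    m
  }
  y <- rep(lobes, 12)
  seqs <- lapply(y, mkSeq)
  cfg <- owgruConfig(layers = 2L, units = 12L, dropout = 0.1,
                     batchSize = 16L, seed = 8)
  m <- trainLocalizer(seqs, y, cfg, epochs = 40, optimizer = "adam",
                      lr = 5e-3)
  pred <- localize(m, seqs)
  acc <- mean(colnames(pred)[max.col(pred)] == y)
  expect_gte(acc, 0.9)
})

test_that("the derived lobe label is the argmax of per-lobe mean response", {
  chans <- c("FP1-F7", "F7-T7", "T7-P7", "P7-O1", "O1-O2")
  expect_identical(deriveLobeLabel(c(5, 5, 0, 0, 0), chans), "frontal")
  # exact two-way tie resolves to the first lobe in the fixed order
  expect_identical(deriveLobeLabel(c(1, 1, 1, 0, 0), chans), "frontal")
  set.seed(9)
  for (i in 1:20) {
    sc <- runif(5)
    lobes <- vapply(chans, mapChannelToLobe, "")
    oracle <- names(which.max(tapply(sc, factor(lobes,
      levels = c("frontal", "temporal", "parietal", "occipital")), mean)))
    expect_identical(deriveLobeLabel(sc, chans), oracle)
  }
  expect_error(deriveLobeLabel(1, "C3-C4"), "excluded")
})

test_that("a single-point search space is returned after one trial", {
  res <- tuneSearch(list(lr = list(type = "categorical", values = list(0.01))),
                    function(p) (p$lr - 0.01)^2, trials = 1, seed = 1)
  expect_identical(res$best$lr, 0.01)
  expect_identical(nrow(res$log), 1L)
})

test_that("the tuner recovers a known optimum within a factor of two", {
  space <- list(lr = list(type = "loguniform", low = 1e-4, high = 1))
  res <- tuneSearch(space, function(p) (p$lr - 0.01)^2, trials = 50, seed = 2)
  expect_gte(res$best$lr, 0.005)
  expect_lte(res$best$lr, 0.02)
  expect_identical(nrow(res$log), 50L)
})

test_that("empty search spaces are rejected and logs carry every trial", {
  expect_error(tuneSearch(list(), function(p) 0), "empty search space")
  res <- tuneSearch(list(x = list(type = "uniform", low = 0, high = 1)),
                    function(p) p$x, trials = 7, seed = 3)
  expect_identical(res$log$trial, 1:7)
  expect_true(all(res$log$value >= 0))
})

test_that("validation-MSE tuning runs end to end on a toy localization set", {
  set.seed(10)
  lobes <- c("frontal", "temporal")
  y <- rep(lobes, 10)
  seqs <- lapply(y, function(lb) {
    m <- matrix(rnorm(8 * 3, sd = 0.3), 8, 3)
    if (lb == "frontal") m[, 1] <- m[, 1] + 2 else m[, 2] <- m[, 2] + 2
    m
  })
  cfg <- owgruConfig(layers = 1L, units = 6L, trials = 3L, seed = 11)
  res <- tuneOWGRU(seqs, y, cfg, epochsPerTrial = 3)
  expect_identical(nrow(res$log), 3L)
  expect_true(is.finite(res$bestValue))
  expect_true(res$bestValue >= 0)
})

test_that("localizer configs validate their invariants", {
  expect_error(owgruConfig(trials = 0), "trials")
  expect_error(owgruConfig(dropout = 1), "dropout")
})
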