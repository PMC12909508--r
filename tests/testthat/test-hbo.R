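iw <- asNamespace("ictalwave")

test_that("fitness is 1 on perfectly separable masked features", {
  fs <- makeFeatureSet(n = 60, delta = 10, seed = 1)
  f <- hboFitness(c(TRUE, TRUE, TRUE, rep(FALSE, 5)), fs$X, fs$y)
  expect_equal(f, 1.0)
})

test_that("fitness is chance-level on permuted labels", {
  fits <- vapply(1:10, function(s) {
    fs <- makeFeatureSet(n = 60, delta = 0, seed = s)   # pure noise
    hboFitness(rep(TRUE, 8), fs$X, fs$y, hboConfig(seed = s))
  }, numeric(1))
  expect_lt(abs(mean(fits) - 0.5), 0.1)
})

test_that("fitness equals an independent rerun of the probe for fixed masks", {
  fs <- makeFeatureSet(seed = 3)
  for (mask in list(c(1, 3), c(2, 5, 8), 1:8)) {
    m <- seq_len(8) %in% mask
    expect_identical(hboFitness(m, fs$X, fs$y),
                     iw$.probeAccuracy(fs$X[, m, drop = FALSE], fs$y, 3L, 1L))
  }
})

test_that("the empty mask scores zero instead of crashing", {
  fs <- makeFeatureSet(seed = 4)
  expect_identical(hboFitness(rep(FALSE, 8), fs$X, fs$y), 0)
})

test_that("a zero step size freezes the exploration update", {
  fs <- makeFeatureSet(seed = 5)
  cfg <- hboConfig(nPop = 4, iterations = 5, stepSize = 0, seed = 2)
  st <- hboInit(fs$X, fs$y, cfg)
  pos0 <- st$positions
  st2 <- explorationStep(st, cfg)
  expect_equal(st2$positions, pos0)
})

test_that("zero gradient with noise disabled leaves positions unchanged", {
  fs <- makeFeatureSet(seed = 6)
  cfg <- hboConfig(nPop = 4, iterations = 5, noise = FALSE, seed = 2)
  st <- hboInit(fs$X, fs$y, cfg,
                gradFn = function(q, state) numeric(length(q)))
  pos0 <- st$positions
  st2 <- explorationStep(st, cfg)
  expect_equal(st2$positions, pos0)
})

test_that("noiseless descent on a convex quadratic improves fitness monotonically", {
  d <- 4
  target <- rep(0.3, d)
  quad <- function(q) sum((q - target)^2)
  cfg <- hboConfig(nPop = 6, iterations = 30, stepSize = 0.05,
                   noise = FALSE, seed = 3)
  st <- hboInit(matrix(0, 2, d), c("a", "b"), cfg,
                fitnessFn = function(q) -quad(q),
                gradFn = function(q, state) 2 * (q - target))
  means <- numeric(20)
  for (i in 1:20) {
    st <- explorationStep(st, cfg)
    means[i] <- mean(st$fitness)
  }
  expect_true(all(diff(means) >= -1e-12))
})

test_that("the honey-phase direction flag follows the draw threshold", {
  expect_identical(iw$.hboMu(0.3), 1)
  expect_identical(iw$.hboMu(0.5), 1)
  expect_identical(iw$.hboMu(0.7), -1)
})

test_that("the density factor reaches theta at the final iteration", {
  expect_identical(iw$.hboDensity(2, 100, 100), 2)
  expect_identical(iw$.hboDensity(2, 50, 100), 1)
})

test_that("an agent sitting on the prey does not move in exploitation", {
  fs <- makeFeatureSet(seed = 7)
  cfg <- hboConfig(nPop = 3, iterations = 5, seed = 4)
  st <- hboInit(fs$X, fs$y, cfg)
  st$positions <- matrix(rep(st$best, each = 3), 3)
  st$fitness <- rep(st$bestFitness, 3)
  st2 <- exploitationStep(st, cfg)
  expect_equal(st2$positions, st$positions)
})

test_that("exploitation only accepts fitness-improving moves", {
  fs <- makeFeatureSet(seed = 8)
  cfg <- hboConfig(nPop = 6, iterations = 10, seed = 5)
  st <- hboInit(fs$X, fs$y, cfg)
  st2 <- exploitationStep(st, cfg)
  expect_true(all(st2$fitness >= st$fitness))
})

test_that("the search matches the exhaustive optimum within 1% on d = 8", {
  for (s in 1:3) {
    fs <- makeFeatureSet(n = 60, d = 8, informative = 1:3, delta = 3,
                         seed = 100 + s)
    cfg <- hboConfig(nPop = 30, iterations = 100, seed = s)
    ex <- hboExhaustive(fs$X, fs$y, cfg)
    run <- hboSelect(fs$X, fs$y, cfg)
    expect_gte(run$bestFitness, ex$bestFitness - 0.01)
  }
})

test_that("the best-so-far fitness trace is non-decreasing", {
  fs <- makeFeatureSet(seed = 9)
  run <- hboSelect(fs$X, fs$y, hboConfig(nPop = 8, iterations = 20, seed = 6))
  expect_true(all(diff(run$trace$bestFitness) >= 0))
  expect_identical(nrow(run$trace), 20L)
})

test_that("identical seeds give identical selected sets", {
  fs <- makeFeatureSet(seed = 10)
  cfg <- hboConfig(nPop = 8, iterations = 15, seed = 7)
  r1 <- hboSelect(fs$X, fs$y, cfg)
  r2 <- hboSelect(fs$X, fs$y, cfg)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$trace, r2$trace)
})

test_that("positions never leave the bounds and the result is never empty", {
  fs <- makeFeatureSet(seed = 11)
  cfg <- hboConfig(nPop = 6, iterations = 12, seed = 8)
  st <- hboInit(fs$X, fs$y, cfg)
  for (i in 1:12) {
    st <- if (i %% 2) explorationStep(st, cfg) else exploitationStep(st, cfg)
    expect_true(all(st$positions >= cfg$bLow & st$positions <= cfg$bHigh))
  }
  run <- hboSelect(fs$X, fs$y, cfg)
  expect_gte(length(run$selected), 1)
})

test_that("informative features are recovered in most seeded runs", {
  hits <- vapply(1:5, function(s) {
    fs <- makeFeatureSet(n = 60, d = 8, informative = 1:3, delta = 3,
                         seed = 200 + s)
    run <- hboSelect(fs$X, fs$y,
                     hboConfig(nPop = 12, iterations = 40, seed = s))
    sum(1:3 %in% run$selected)
  }, numeric(1))
  expect_gte(sum(hits >= 2), 4)
})

test_that("degenerate configurations are rejected", {
  expect_error(hboConfig(nPop = 1), "at least 2")
  expect_error(hboConfig(bLow = 1, bHigh = 0), "bLow")
  fs <- makeFeatureSet(seed = 12)
  expect_error(hboSelect(fs$X[, integer(0), drop = FALSE], fs$y),
               "at least one feature")
})
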