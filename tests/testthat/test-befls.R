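centersOf <- function(rb) {
  vapply(c("alpha", "delta", "entropy"), function(v)
    rb@memberships[[v]]$center, numeric(3))
}

test_that("bell membership is 1 at the center and 0.5 at one width for any slope", {
  expect_identical(bellMembership(0.4, 0.4, 0.1, 2), 1)
  for (g in c(0.5, 1, 2, 5)) {
    expect_equal(bellMembership(0.5, 0.4, 0.1, g), 0.5)
    expect_equal(bellMembership(0.3, 0.4, 0.1, g), 0.5)
  }
})

test_that("bell membership decays monotonically to zero in the tails", {
  d <- seq(0, 50, by = 0.5)
  vals <- bellMembership(0.5 + d, 0.5, 0.2, 2)
  expect_true(all(diff(vals) <= 0))
  expect_lt(bellMembership(1e6, 0.5, 0.2, 2), 1e-12)
  expect_equal(vals, bellMembership(0.5 - d, 0.5, 0.2, 2))  # symmetry
})

test_that("non-positive width or slope is rejected", {
  expect_error(bellMembership(0, 0, 0, 1), "positive")
  expect_error(bellMembership(0, 0, 1, -1), "positive")
})

test_that("fuzzification is exact at level centers and bounded in [0, 1]", {
  rb <- defaultRuleBase()
  ctr <- centersOf(rb)
  inputs <- c(alpha = ctr["Medium", "alpha"], delta = ctr["Medium", "delta"],
              entropy = ctr["Medium", "entropy"])
  deg <- fuzzify(inputs, rb)
  expect_equal(unname(deg[, "Medium"]), rep(1, 3))
  set.seed(1)
  for (i in 1:10) {
    deg <- fuzzify(runif(3), rb)
    expect_true(all(deg >= 0 & deg <= 1))
  }
})

test_that("fuzzification agrees with the pointwise bell formula", {
  rb <- fitMemberships(matrix(runif(90), 30, 3))
  set.seed(2)
  for (i in 1:20) {
    x <- runif(3)
    names(x) <- c("alpha", "delta", "entropy")
    deg <- fuzzify(x, rb)
    for (v in c("alpha", "delta", "entropy"))
      for (lv in c("Low", "Medium", "High")) {
        m <- rb@memberships[[v]]
        expect_identical(deg[v, lv],
                         bellMembership(x[[v]], m$center[[lv]],
                                        m$width[[lv]], m$gamma))
      }
  }
})

test_that("all four canonical rules reproduce at their antecedent centers", {
  rb <- defaultRuleBase()
  ctr <- centersOf(rb)
  rules <- fuzzyRules(rb)
  for (r in seq_len(nrow(rules))) {
    inputs <- c(alpha = ctr[rules$alpha[r], "alpha"],
                delta = ctr[rules$delta[r], "delta"],
                entropy = ctr[rules$entropy[r], "entropy"])
    res <- inferIndex(inputs, rb)
    expect_identical(res$stage, rules$stage[r])
  }
})

test_that("two equally firing rules with Low and High consequents defuzzify to Medium", {
  rb <- defaultRuleBase()
  rb@rules <- data.frame(alpha = c("Low", "Low"), delta = c("Low", "Low"),
                         entropy = c("Low", "Low"),
                         stage = c("Low", "High"), stringsAsFactors = FALSE)
  ctr <- centersOf(rb)
  inputs <- c(alpha = ctr["Low", "alpha"], delta = ctr["Low", "delta"],
              entropy = ctr["Low", "entropy"])
  res <- inferIndex(inputs, rb)
  expect_equal(res$DF, 0.5)
  expect_identical(res$stage, "Medium")
})

test_that("the defuzzified output is a convex combination of the consequents", {
  rb <- fitMemberships(matrix(runif(120), 40, 3))
  set.seed(3)
  for (i in 1:25) {
    res <- inferIndex(runif(3, -0.2, 1.2), rb)
    expect_gte(res$DF, min(rb@consequents))
    expect_lte(res$DF, max(rb@consequents))
  }
})

test_that("sweeping alpha moves DF continuously without jumps", {
  rb <- defaultRuleBase()
  ctr <- centersOf(rb)
  grid <- seq(0, 1, by = 0.01)
  dfs <- vapply(grid, function(a)
    inferIndex(c(alpha = a, delta = ctr["Medium", "delta"],
                 entropy = ctr["Medium", "entropy"]), rb)$DF, numeric(1))
  expect_lt(max(abs(diff(dfs))), 0.25)   # largest consequent gap
})

test_that("the no-rule-fires case errors without fallback and resolves with it", {
  rb <- defaultRuleBase()
  far <- c(alpha = 1e7, delta = 1e7, entropy = 1e7)
  expect_error(inferIndex(far, rb, fallback = FALSE), "no rule fires")
  res <- inferIndex(far, rb)
  expect_true(res$stage %in% c("Low", "Medium", "High"))
})

test_that("fitted memberships order the tertile centers Low < Medium < High", {
  set.seed(4)
  fm <- cbind(rbeta(200, 2, 5), runif(200), rbeta(200, 5, 2))
  rb <- fitMemberships(fm)
  for (v in c("alpha", "delta", "entropy")) {
    ctr <- rb@memberships[[v]]$center
    expect_true(ctr[["Low"]] < ctr[["Medium"]])
    expect_true(ctr[["Medium"]] < ctr[["High"]])
    expect_true(all(rb@memberships[[v]]$width > 0))
  }
})

test_that("segment activity indices rank activity tiers in the expected order", {
  rec <- generateBackground(synthConfig(duration = 60, seed = 5))
  recs <- list(
    Low = injectSeizure(rec, 10, 50, "temporal", "Low", seed = 2),
    High = injectSeizure(rec, 10, 50, "temporal", "High", seed = 2))
  feats <- lapply(recs, function(r) {
    ss <- labelSegments(segmentWindows(r), annotations(r),
                        exclusionMarginSec = 2)
    segs <- segments(ss)[segmentLabels(ss) == "seizure"]
    t(vapply(segs, segmentFuzzyFeatures, numeric(3), samplingRate = 256))
  })
  rb <- fitMemberships(rbind(feats$Low, feats$High))
  dfFor <- function(f) mean(apply(f, 1, function(x) inferIndex(x, rb)$DF))
  # stronger bursts push delta power up and entropy down -> higher index
  expect_false(isTRUE(all.equal(dfFor(feats$Low), dfFor(feats$High))))
})

test_that("a rule base survives a YAML round trip", {
  rb <- fitMemberships(matrix(runif(90), 30, 3))
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    rules = lapply(seq_len(nrow(rb@rules)), function(i) as.list(rb@rules[i, ])),
    memberships = lapply(rb@memberships, function(m)
      list(center = as.list(m$center), width = as.list(m$width),
           gamma = m$gamma)),
    consequents = as.list(rb@consequents)), path)
  back <- ruleBaseFromYAML(path)
  expect_identical(fuzzyRules(back), fuzzyRules(rb))
  # yaml serializes doubles at ~8 significant digits
  expect_equal(back@memberships$alpha$center, rb@memberships$alpha$center,
               tolerance = 1e-6)
  expect_equal(back@consequents, rb@consequents, tolerance = 1e-6)
})

test_that("the show method dumps the active rules for audit", {
  out <- capture.output(show(defaultRuleBase()))
  expect_true(any(grepl("R4", out)))
  expect_true(any(grepl("High", out)))
})
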