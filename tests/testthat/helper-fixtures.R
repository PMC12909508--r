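# Shared fixture builders (all generated in code, seeded).

# Tiny annotated recording: 30 s, 8 channels, one temporal seizure.
makeTinyRecording <- function(seed = 1L, duration = 30, level = "Medium",
                              lobe = "temporal", onset = 10, offset = 18) {
  cfg <- synthConfig(duration = duration, seed = seed)
  injectSeizure(generateBackground(cfg), onset, offset, lobe, level,
                seed = seed + 1L)
}

# Gaussian two-class features: columns `informative` carry the class
# signal (mean shift `delta`), the rest are pure noise.
makeFeatureSet <- function(n = 60, d = 8, informative = 1:3, delta = 3,
                           seed = 1L) {
  set.seed(seed)
  y <- rep(c("a", "b"), length.out = n)
  X <- matrix(rnorm(n * d), n, d)
  X[y == "b", informative] <- X[y == "b", informative] + delta
  list(X = X, y = y)
}

# Small backbone config for structural/unit tests.
tinyBackboneConfig <- function(seed = 1L) {
  backboneConfig(inputSize = c(32L, 32L), scale = 0.0625,
                 baseBlocks = c(1L, 1L, 1L, 1L), initialStride = 1L,
                 stageStrides = c(1L, 2L, 2L, 1L), seed = seed)
}

# Sparse spike train plus scaled white noise at a given input SNR (dB).
makeSpikySignal <- function(n = 1024, snrDb = 0, seed = 1L) {
  clean <- numeric(n)
  clean[seq(40, n - 24, by = 85)] <- 5
  set.seed(seed)
  noise <- rnorm(n)
  noise <- noise * sqrt(sum(clean^2) / sum(noise^2) / 10^(snrDb / 10))
  list(clean = clean, noisy = clean + noise)
}

snrDb <- function(clean, x) 10 * log10(sum(clean^2) / sum((x - clean)^2))

# Periodogram band power (independent of the package's implementation).
oracleBandPower <- function(x, fs, lo, hi) {
  p <- Mod(fft(x))^2
  f <- (seq_along(x) - 1) * fs / length(x)
  keep <- f <= fs / 2
  sum(p[keep & f >= lo & f <= hi])
}
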