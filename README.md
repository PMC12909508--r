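# ictalwave

EEG seizure analysis in R: dual-tree complex wavelet denoising,
annotation-driven segmentation, spectrogram deep-feature extraction,
metaheuristic wrapper feature selection, seizure detection, a fuzzy
Low/Medium/High seizure-activity index, and localization of epileptic
activity to a cerebral lobe.  Written for signal-processing and
machine-learning researchers who need a fully testable seizure pipeline:
a synthetic-EEG generator with lobe-localized ~3 Hz spike-wave bursts
makes every stage verifiable without access to clinical recordings.

## What it computes

For a multichannel scalp EEG recording with 10–20-system channel names,
the pipeline answers three questions per 2-second window:

* **Detection** — seizure vs background.  Windows (50% overlap) are
  denoised with a dual-tree complex wavelet transform
  (Ψ = Ψ_h + iΨ_g; four decimated complex detail sub-bands D1…D4 plus
  an approximation A4; soft-thresholding of |D_k| at the universal
  threshold σ_k√(2 log N_k)), rendered as 0–30 Hz Hamming-window STFT
  spectrograms (256/256/128), passed through a 182-layer
  inception-residual backbone with a ConvLSTM refinement stage, and
  classified by a softmax head on honey-badger-selected deep features.
  The feature search follows stochastic variance-reduced gradient
  Langevin dynamics in exploration, `q − ϖ∇λ + √(2ϖ)·h`, and the greedy
  honey phase `prey + μ·x2·(θ·t/T)·|prey − q|` in exploitation.
* **Activity index** — a Mamdani fuzzy system over relative alpha
  power, relative delta power and spectral entropy with generalized-bell
  memberships `1/(1 + (|v−λ|/β)^(2γ))`, four canonical rules, and
  weighted-average defuzzification `DF = Σ R_r c_r / Σ R_r` onto
  consequents 0.25/0.50/0.75 → Low/Medium/High.  A signal-derived
  relative tier, not a clinical severity score.
* **Localization** — a four-layer, 50-unit stacked GRU whose candidate
  state uses a sine ("wave") activation,
  `ch = sin(K_c·[r⊙h, x])`, `h = (1−u)⊙h + u⊙ch`, over per-lobe
  band-power sequences with the fuzzy index appended, softmax over
  {frontal, temporal, parietal, occipital}.

See `vignette("seizure-pipeline")` for the full methods account,
parameter defaults and limitations.

## Worked example

```r
library(ictalwave)

## a 60 s, 8-channel synthetic recording with one temporal-lobe seizure
cfg <- synthConfig(duration = 60, seed = 1)
rec <- generateBackground(cfg)
rec <- injectSeizure(rec, onset = 20, offset = 32,
                     lobe = "temporal", level = "High")

## denoise, segment, label
den  <- denoiseRecording(lowpassFilter(rec))
segs <- labelSegments(segmentWindows(den), annotations(rec),
                      exclusionMarginSec = 10)
segs
#> SegmentSet: 59 segments of 2 s (overlap 50%) @ 256 Hz
#>   seizure 13 | non-seizure 26 | excluded 20 | unlabeled 0
```

The 12-s event covers 13 overlapping windows; windows within 10 s of it
are excluded from the background class.  The fuzzy index and the
electrode-level lobe rule:

```r
feats <- t(vapply(segments(segs), segmentFuzzyFeatures, numeric(3),
                  samplingRate = 256))
rb  <- fitMemberships(feats)        # tertile-fitted bell memberships
idx <- segmentActivityIndex(segs, rb)
table(label = segmentLabels(segs), stage = idx$stage)
#>              stage
#> label         High Low Medium
#>   excluded       2   0     18
#>   non-seizure    2   0     24
#>   seizure        0   1     12

score <- apply(eegData(rec)[, (20*256):(32*256)], 1, bandPower,
               samplingRate = 256, band = c(2, 4), relative = FALSE)
deriveLobeLabel(score, channelNames(rec))
#> [1] "temporal"
```

The in-burst 2–4 Hz power concentrates on the two temporal channels, so
the average-response rule recovers the injected lobe.  The full
benchmark — 10 subjects, subject-wise 7/1/2 split, brief backbone
training, feature selection, detection and localization on the held-out
subjects — runs in a few minutes on one CPU:

```r
report <- runPipeline(pipelineConfig(seed = 1))
report
#> Pipeline report
#>   detection  (n=118): AC 0.992 | PR 1.000 | RE 0.981 | SP 1.000 | F1 0.990 | MCC 0.983
#>   localization (n=52): accuracy 0.942
#>   selected features: 23 | best fitness 0.991
```

`n = 118` test windows come from the two held-out subjects; detection
accuracy, precision, recall, specificity, F1 and Matthews correlation
are computed from the seizure-vs-background confusion counts, and
localization accuracy over the 52 held-out seizure windows against the
injected lobes.  A thin CLI wraps the same functions:
`exec/ictalwave synth|run-all|evaluate`.

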