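# ecogseg

Where on the cortex, and when relative to each spoken phoneme, does brain
activity differ between speech sounds that do and do not carry a given
**segmental feature** — place of articulation (labial / coronal / dorsal),
manner (obstruent / sonorant), voicing, or the consonant/vowel class?
`ecogseg` answers this question from multi-channel electrocorticographic
(ECoG) recordings of continuous speech, using the 70–170 Hz gamma band as
the activation signal. It is written for electrophysiologists and
speech-BCI researchers who have (or simulate) a channels × samples
recording plus a phoneme alignment table.

## Method

For each feature dimension, phoneme-locked 700 ms epochs of log gamma
power (350 ms either side of acoustic onset) are labelled "+"/"−" and
classified:

* per-epoch features are 50 ms bin means of log gamma power
  (25 ms steps → 27 bins per electrode spatially; 10 ms steps → 66 bins
  temporally);
* minimum-redundancy maximum-relevance (mRMR, difference form,
  tertile-discretized mutual information) selects features inside each
  training fold;
* a shrinkage-regularized LDA, *w* = Σ̂⁻¹(μ₊ − μ₋) with the Ledoit–Wolf
  estimate Σ̂ = (1−λ)S + λ(tr S/d)I, is scored by stratified 5-fold
  cross-validated ROC AUC ("+" positive);
* the AUC is tested against 0.5 with the Hanley–McNeil standard error,
  √[(A(1−A) + (n₊−1)(Q₁−A²) + (n₋−1)(Q₂−A²))/(n₊n₋)],
  Q₁ = A/(2−A), Q₂ = 2A²/(1+A), Benjamini–Hochberg corrected, and
  converted to an **activation index** ψ(p) = −ln p for p < 0.01 (else 0);
* spatial maps accumulate per-electrode AIs across subjects; temporal
  profiles average per-latency-bin AIs across significant electrodes and
  report the peak latency and local maxima.

Subjects enter the feature analyses only if a speech-vs-silence screening
classifier (word-locked vs. silence epochs, 50 mRMR features over all
electrodes) exceeds AUC 0.8:

```r
screening_from_auc(c(A = 0.57, B = 0.81, C = 0.51, D = 0.68,
                     E = 0.91, F = 0.87, G = 0.91))
#>   subject   auc passed
#> 1 A        0.57 FALSE
#> 2 B        0.81 TRUE     ... 4 of 7 subjects pass
```

A fully seeded synthetic-data generator (1/f background, 60/120/180 Hz
line noise, per-grid common mode, phoneme-locked gamma bursts with known
electrodes/latency/gain) makes the whole chain testable with ground truth.
See the vignette `vignettes/segmental-feature-mapping.Rmd` for the design
rationale behind every parameter.

## Worked example

Simulate a 16-electrode, 90 s session with a voicing-locked gamma burst
(gain 2, 60–140 ms after onset) at electrodes 4 and 11, then run the full
pipeline:

```r
library(ecogseg)

cfg <- sim_config(
  n_electrodes = 16, duration_s = 90, seed = 1,
  effects = list(sim_effect("voiced", electrodes = c(4, 11),
                            gain = 2, latency_ms = 60, duration_ms = 80))
)
sess <- simulate_session(cfg)

screen_subject(sess$recording, sess$words, seed = 1)
#> <screening_result> speech-vs-silence CV AUC = 0.971 (threshold 0.80): PASSED

prep <- preprocess_recording(sess$recording)
es27 <- phoneme_epochs(prep, sess$alignments, bin_ms = 50, step_ms = 25)
amap <- spatial_analysis(es27, "voiced", seed = 1,
                         coords = sess$recording$coords)
dplyr::filter(amap, significant)
#> # A tibble: 2 × 11
#>   subject electrode dimension     x     y   auc      se     p p_adj     ai
#> 1 <NA>            4 voiced       30     0 0.996 0.00263     0     0 17786.
#> 2 <NA>           11 voiced       20    10 0.999 0.00156     0     0 51007.

es66 <- phoneme_epochs(prep, sess$alignments, bin_ms = 50, step_ms = 10)
temporal_analysis(es66, "voiced",
                  electrodes = amap$electrode[amap$significant], seed = 1)
#> <temporal_profile> 'voiced', 2 electrodes: peak AI 31850.61 at +95 ms
#>   local maxima at: +95 ms
```

Exactly the two implanted effect electrodes are recovered with no false
positives among the 16 channels, and the temporal profile peaks at
+95 ms — the burst window's midpoint (60 + 80/2 = 100 ms) to bin
resolution. The enormous activation indices reflect the deliberately
strong synthetic effect (AUC ≈ 1 ⇒ vanishing p); weak effects produce the
familiar single- to double-digit AIs. `autoplot()` renders activation
maps and temporal profiles; `tidy()`/`glance()` return the underlying
tibbles.

A thin command-line front end with `simulate` / `screen` / `spatial` /
`temporal` subcommands is installed at `inst/cli/ecogseg.R`.

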