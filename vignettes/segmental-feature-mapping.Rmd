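---
title: "Mapping speech segmental features from ECoG gamma power: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping speech segmental features from ECoG gamma power: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecogseg)
```

## The problem

During fluent speech, dozens of articulatory events overlap in time: lips
close while the tongue is already moving toward the next constriction and the
larynx switches voicing on and off. `ecogseg` asks where on the cortical
surface, and when relative to each phoneme's acoustic onset, electrical
activity *differs* between phonemes that do and do not carry a given
segmental feature — place of articulation (labial, coronal, dorsal), manner
(obstruent vs. sonorant), voicing, and the phonological consonant/vowel
class. The carrier signal is the 70–170 Hz gamma band of subdurally recorded
ECoG, whose power tracks local cortical activation with millisecond
resolution.

The package implements the full analysis as a tested pipeline — phoneme
feature coding, signal conditioning, epoch extraction, classification,
significance statistics, and spatial/temporal activation maps — together
with a synthetic-data generator that produces recordings with known ground
truth, so that every stage can be validated end to end without access to
patient data.

## Phoneme inventory and feature coding

The compiled inventory is the General American set: 24 consonants and
15 vowels, ARPAbet-coded with IPA display forms. Feature assignment is
binary per dimension; a phoneme may carry several "+" features at once
(/w/ is labial *and* dorsal), vowels carry no place feature, and the
obstruent/sonorant pair partitions the inventory exhaustively. Two details
are deliberate choices:

* voicing follows standard English phonology (/z/, /ʒ/, /ð/ voiced; /ʃ/,
  /θ/ voiceless), overriding a pair of internally inconsistent assignments
  sometimes seen in printed feature tables;
* /h/ is classed as a voiceless obstruent so that the manner partition has
  no gaps.

Labels are attached per alignment row by `label_for_feature()`; "+" is the
positive class throughout. For the phonological contrast the positive class
is the vowel set, exposed as dimension `"vowel"` (the complement of
`"consonant"` — AUC-based results are unaffected by which side is called
positive, but plots and signs read more naturally this way).

## Signal chain

`preprocess_recording()` applies, in order:

1. **High-pass**, 0.5 Hz cutoff, Butterworth order 4, zero-phase
   (forward–backward), removing DC and electrode drift.
2. **Notch** at 120 Hz, second-order IIR with quality factor
   Q = f₀/bandwidth = 35 (≈3.4 Hz wide). 120 Hz is the only power-line
   component inside the analysis band; 60, 180 and 240 Hz are left alone
   because the pipeline never looks there.
3. **Common-average reference per grid**: at every sample the mean across a
   grid's channels is subtracted from that grid's channels. Grids are
   referenced independently, so shared noise in one grid cannot leak into
   another.
4. **Gamma log power**: 70–170 Hz Butterworth band-pass (order 4,
   zero-phase), squaring, then the natural log.

Zero-phase filtering is implemented with odd-extension padding plus exact
steady-state initial conditions, and the channel mean is routed through the
filter's DC gain analytically. This matters numerically: a fourth-order
0.5 Hz recursion driven by a signal with a large offset suffers
catastrophic cancellation, and naive forward–backward filtering leaves
edge transients that ring for seconds at that cutoff. A floor of
ε = 1e-12 (signal units²) is added before the log so exact zeros map to
log ε rather than −∞; the value is far below any physiological in-band
power, and bin averages are insensitive to it.

## Epochs and binning

Epochs are 700 ms windows, half-open `[onset − 350 ms, onset + 350 ms)`,
aligned to phoneme onsets. Overlapping epochs from adjacent phonemes are
all kept — continuous speech *is* overlapping — and windows that would run
past a recording edge are dropped (never padded) and counted.

Within each epoch, log gamma power is averaged in 50 ms bins. Two binnings
are used: 25 ms steps give 27 bins per electrode (the spatial feature set),
and 10 ms steps give 66 bins (the temporal analysis). Bin counts follow
`floor((700 − 50)/step) + 1`. Bins are labelled by their temporal midpoint,
so the 66-bin grid runs −325 … +325 ms in 10 ms steps; reported peak
latencies live on that grid.

## Classification engine

Each contrast is a binary classification of epochs. The engine is
deliberately simple and fixed — no hyper-parameter search:

* **mRMR feature selection** (difference form): greedy forward selection
  maximizing `MI(feature; label) − mean MI(feature; selected)`, with
  plug-in mutual information on 3-level quantile-discretized features.
  Tertiles are the common default for continuous neural features, and the
  discrete plug-in estimator is the canonical form for this criterion;
  ties break toward the lowest feature index so selection is
  deterministic.
* **Shrinkage LDA**: the discriminant direction is
  `w = Σ̂⁻¹(μ₊ − μ₋)` with the pooled within-class covariance replaced by
  its Ledoit–Wolf shrunk estimate `Σ̂ = (1−λ)S + λ·(tr S/d)·I`. λ is
  estimated once from the pooled class-centered residuals (standard
  shrinkage-LDA practice) and clipped to [0, 1]. With a single feature
  the target equals S, λ is 0, and the classifier reduces to plain LDA —
  which is why the temporal analysis needs no explicit regularization.
  The bias uses empirical training-fold priors; AUC is threshold-free, so
  this affects only hard predictions.
* **Cross-validation**: 5 stratified folds (stratification protects rare
  classes such as dorsal at ~12% of consonants); feature selection and
  fitting happen inside each training fold only, and performance is the
  mean over folds of the test-fold ROC AUC.

## Statistics

AUC is computed as the normalized Mann–Whitney statistic (ties count ½).
Its standard error uses the Hanley–McNeil closed form with
Q₁ = A/(2−A), Q₂ = 2A²/(1+A). The test against chance is one-sided
(A > 0.5): the pipeline only ever asks whether discrimination is *above*
chance, and a two-sided option is available. P-values are
Benjamini–Hochberg adjusted; the multiplicity family is an argument (`m`)
so that pooled analyses can correct over subjects × electrodes (spatial)
or subjects × bins × significant electrodes (temporal) as one family.

The activation index is `ψ(p) = −ln p` when the *adjusted* p is strictly
below 0.01, else 0. Applying the threshold to the corrected p keeps the
index consistent with the multiplicity control; the inequality is strict,
so `activation_index(0.01)` is exactly 0. Internally the normal tail and
the BH step-up run on the log scale: synthetic effects can be strong
enough that p underflows double precision, and the log path keeps
activation indices finite and ordered where `-log(exp(...))` would return
`Inf`.

## Study-level analyses

* **Screening** (`screen_subject()`): word-locked 700 ms epochs vs. an
  equal number of silence epochs, all electrodes' 27 bins pooled, mRMR
  selects 50 features, 5-fold CV; a subject passes if the AUC exceeds 0.8
  (strictly). Silence windows are drawn without replacement from
  non-overlapping 700 ms slots in the pauses between words; because
  realistic pause structure yields fewer slots than words, the larger
  class is subsampled (seeded) so classes stay balanced, and an error
  listing the available count is raised if fewer than 10 slots exist.
* **Spatial topography** (`spatial_analysis()`): per electrode, 27 bins →
  mRMR 10 → CV AUC → p → BH → AI. Place runs three one-vs-rest contrasts;
  manner, voicing and the phonological class are single contrasts.
* **Temporal dynamics** (`temporal_analysis()`): restricted to the
  spatially significant electrodes; per (electrode, bin of 66) a
  single-feature LDA CV, then the same p → BH → AI path; the profile is
  the mean AI across electrodes per latency bin. The peak is the profile
  maximum; local maxima are strict local maxima of the 3-bin
  moving-average-smoothed profile with topographic prominence ≥ 0.5 AI
  units (a profile criterion has to be fixed somewhere; this one ignores
  one-bin ripples while keeping genuine secondary peaks).
* **Pooling** (`accumulate_across_subjects()`): per-subject maps are
  overlaid in the shared coordinate frame and significant electrodes are
  tallied per dimension. No surface interpolation is attempted —
  template-brain projection is out of scope.

## The synthetic-data generator

`sim_config()` + `simulate_session()` produce recordings with the
statistical structure the analysis assumes, and nothing more:

* **1/f background** per electrode (default exponent 1.5, SD 20 a.u.,
  spectrum flattened below 1 Hz), generated by spectral shaping;
* **line noise** at 60/120/180 Hz (default amplitudes 5/2/1 a.u., common
  phase, per-channel amplitude jitter);
* **per-grid common mode** (default SD 15 a.u.) shared by all channels of
  a grid — the component CAR must remove;
* **phoneme-locked effects**: band-limited 70–170 Hz Gaussian-noise bursts
  added in `[onset + latency, onset + latency + duration)` of
  positive-class phonemes, with amplitude `gain` × the channel's in-band
  background amplitude. Bursts are multiplicative-scale amplitude events,
  not added sinusoids, because real high-gamma is broadband and the
  analysis measures band power. The default gain of 2 corresponds to a
  ~5× in-band power increase during the burst — a strong but realistic
  task response. Because a burst raises power over its whole window, the
  expected AI peak sits at the window *midpoint*, `latency +
  duration/2`; the ground-truth table carries this as
  `expected_peak_ms`, and recovery is judged against it.

Phoneme sequences use a vowel fraction of 39.2% and English-like
consonant weights giving ≈23% labial, ≈65% coronal and ≈12% dorsal among
consonants. (The three place fractions cannot all be matched exactly by
any distribution over this inventory once /w/'s double membership and
/h/'s non-membership are accounted for; the weights are fixed once and
the tests check realized fractions against the weights' own
implications.) Words are 2–8 phonemes; inter-word gaps are 150–350 ms
with longer 0.9–1.8 s pauses interspersed (probability 0.3) so the
screening has silence windows to draw on. Everything is derived from a
single integer seed, and a configuration with all gains 0 produces, at
the same seed, exactly the same samples as a no-effect configuration.

What the generator does **not** emulate: coarticulation beyond window
overlap, epileptiform or movement artifacts, electrode-specific
impedance drift, spatially correlated background beyond the grid common
mode, and any acoustic signal. Passing recovery tests therefore
demonstrates that the pipeline detects and localizes band-power effects
of the assumed form under realistic noise — not that it is robust to
every pathology of clinical recordings.

One consequence of the signal model worth knowing: CAR subtracts 1/48 of
every effect burst from all channels of the grid, so a large set of
strong effect electrodes bleeds a label-correlated trace into the
reference. With a handful of effect electrodes the bleed is far below
detection threshold; recovery tests use small active sets for this
reason, matching typical focal task responses.

## Problem sizes and determinism

The test suite and the reproduction script run the full chain at sizes
chosen to exercise every code path with comfortable statistical power:
null-calibration runs use 12-electrode, 50 s sessions over 20 seeded
replicates; recovery runs use a 48-electrode, 90 s session (~400 phoneme
epochs); the chance-level reproduction uses 48 electrodes, 400 epochs and
20 replicates. All randomness — alignments, noise, fold assignment,
silence placement, label permutation — is derived from user-supplied
integer seeds, and repeated runs are bit-identical.

## Known limitations

* Alignments are consumed as input (or simulated); forced alignment of
  real audio is out of scope.
* The pipeline assumes the 1200 Hz nominal sampling rate divides the
  50/25/10 ms bin grid exactly; other rates must keep `step × fs` integral.
* Electrode coordinates are planar template positions; no anatomical
  surface model or atlas projection is provided.
* Sub-category features (e.g. bilabial vs. labiodental, stop vs.
  fricative) are not coded in the feature table.
* The Hanley–McNeil normal approximation is anti-conservative for AUCs
  very near 1 with few observations; with the epoch counts used here the
  BH step keeps the realized false-positive rate at or below nominal in
  the null-calibration tests.
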