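---
title: "Simulating and analysing multi-feature MMN oddball EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing multi-feature MMN oddball EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmnpipe)
```

## The scientific problem

During speech perception the brain predicts both *what* comes next (formal
predictions, e.g. which phoneme sequences are likely) and *when* it comes
(temporal predictions, e.g. which syllable carries stress). The mismatch
negativity (MMN) — a frontocentral negative ERP deflection roughly
100–250 ms after an auditory deviation — indexes how readily the auditory
system detects a violation of such predictions, without requiring the
listener's attention.

`mmnpipe` implements a complete analysis chain for a passive multi-feature
oddball design built on a quadruplet of bisyllabic pseudowords crossing
**phonotactic probability** (the medial cluster `-ts-` is frequent in
Dutch, hence high-probability, HPP; `-tk-` is rare, LPP) with **syllable
stress** (first, SylStr1, vs. second, SylStr2, upper case marks stress):
`NOTsal`, `NOTkal`, `notSAL`, `notKAL`. Each stimulus serves as the
standard of one condition; within that condition the *formal deviant*
differs only in the cluster and the *temporal deviant* only in stress.
Because every stimulus reappears as a deviant in other conditions, the
analysis can compare the *identical* stimulus as standard vs. deviant,
isolating the prediction violation from acoustic differences
(`build_identity_map()`).

Since no public recordings accompany this design, the package includes a
synthetic-EEG generator with known ground truth, so every stage —
sequence generation, preprocessing, trial selection, ERP measurement,
inference — is verifiable end to end.

## The oddball design

One condition comprises 1,620 trials: 1,332 standards and 144 deviants per
type (8.9%), delivered in 1,200 ms trials (600 ms stimulus, 600 ms
inter-stimulus interval), with any two successive deviants separated by 1–8
standards. `generate_condition_sequence()` enforces these tallies exactly.

The separation distribution over 1–8 is not uniquely determined by the
constraints; the default `balanced = TRUE` allocates each deviant type's
separations equally (144/8 = 18 per separation). This choice makes the
downstream selection arithmetic exact: deviants preceded by only one
standard are excluded from analysis, so 18 deviants per type drop and
`select_analysis_trials()` retains 126 per type, with the 2 × 126 = 252
immediately preceding standards forming the condition's standard pool.
Both deviant types are interleaved in one block, and the separation
constraint applies between successive deviants of either type. Run/block
bookkeeping (3 runs × 4 blocks × 270 trials × 2 sessions) is metadata;
analysis pools trials across blocks. Token variants (3 utterances per
stimulus) are assigned uniformly at random, as no allocation scheme is
implied by the design.

## The synthetic-EEG generator

`simulate_subject()` produces continuous multichannel EEG for a sequence:

* **Montage** — 57 scalp electrodes on schematic 10%-grid positions plus
  M1/M2 mastoids and 4 EOG channels (63 in total), 1000 Hz sampling.
* **Obligatory responses** — N1 (−4 µV, 100 ms, FWHM 50 ms) and P2
  (+3 µV, 200 ms, FWHM 80 ms) after each syllable onset. The second
  syllable is placed at 300 ms (half of the 600 ms stimulus); the true
  syllable timing of the recorded stimuli is unknown, and these components
  are nuisance terms that cancel exactly in identical-stimulus difference
  waves.
* **MMN ground truth** — per phonotactic-probability × stress ×
  deviant-type cell, a negative Gaussian deflection (default FWHM 60 ms)
  centred at deviation onset + true latency. The deviation onset is the
  /t/-onset (250 ms) for formal deviants and stimulus onset for temporal
  deviants. Defaults place formal-deviant peaks at 160 ms (HPP) vs 200 ms
  (LPP) — an earlier response for the high-probability cluster, the
  qualitative pattern this paradigm is designed to detect — with
  amplitudes −2.5/−3.0 µV, and temporal-deviant peaks at 250 ms with
  −2.8/−2.3 µV. A Gaussian was chosen because its peak latency is
  unambiguous, exercising the peak-search windows cleanly.
* **Topography** — Gaussian radial falloff from FCz (the canonical MMN
  maximum), weight 1 at FCz, ≈0.9 on the frontal row, ≈0.7
  centroparietally; mastoids get weight 0 by default so the
  average-mastoid reference is neutral for signal.
* **Noise** — per-channel 1/f (pink) noise synthesized in the frequency
  domain (default SD 10 µV, a typical ongoing-EEG magnitude), common-phase
  50 Hz line noise (2 µV), and Poisson ocular blinks (12/min, 150 µV
  raised-cosine templates on the vertical EOG, decaying onto frontal scalp
  rows).

What the generator does **not** emulate: spatially correlated background
sources (noise is independent across channels), real head geometry or
volume conduction, muscle or electrode artifacts other than blinks,
stimulus acoustics, and drifting vigilance. Passing tests therefore show
the *pipeline* is correct and calibrated under the stated noise model, not
that real recordings would yield these effect sizes.

## Preprocessing choices

The chain runs in a fixed order: band-pass + notch filter → downsample to
250 Hz → ocular-artifact removal → epoch → DC/baseline correction →
75 µV amplitude rejection → average-mastoid re-reference.

* **Filtering** (0.5–70 Hz band-pass, 48–52 Hz notch) must be zero-phase,
  because MMN *latency* is an outcome measure. The default realization
  multiplies each channel's spectrum by the squared magnitude response of
  the Butterworth cascade (2nd-order high- and low-pass, 2nd-order
  band-stop) — the exact frequency-domain counterpart of forward–backward
  IIR filtering, vectorized over channels. A time-domain
  `signal::filtfilt` path (`method = "iir"`) is kept as an independent
  cross-check; the two agree away from the record edges.
* **Epochs** are half-open `[−100, 1000)` ms windows, i.e. 275 samples at
  250 Hz. The convention is fixed so sample counts are exact and testable.
* **DC + baseline correction** subtracts the epoch mean and then the
  `[−100, 0)` ms baseline mean; algebraically this equals subtracting the
  baseline mean alone, and leaves baseline means exactly zero.
* **The 75 µV criterion** is applied to the 57 scalp channels only
  (mastoids and EOG excluded) and *before* re-referencing, following the
  order in which the steps are described for this paradigm.
* **Ocular artifacts** — the original workflow used ICA with manual
  component selection, which is not reproducible in software. The
  automated surrogate (`ica_auto`) decomposes all channels into as many
  components as channels with a seeded FastICA and removes every component
  whose time course correlates with an EOG channel at |r| ≥ 0.7. A
  least-squares `eog_regression` and `none` are also available; the
  full-scale profile defaults to regression and the blink-free scaled
  profile to `none`.

## Trial selection and equalization

Deviants preceded by a single standard are excluded; standards are kept
only if they immediately precede a kept deviant. `equalize_counts()` then
subsamples every deviant cell and every condition's standard pool to one
**global minimum** across all 8 deviant cells of the participant. Reading
the equalization target as a single per-participant minimum (rather than
per condition) yields the strict cross-condition balance the
repeated-measures amplitude ANOVA assumes. One standard subset per
condition is drawn and shared between the formal- and temporal-deviant
comparisons, so both are measured against the same standard trials. If a
standard preceding a kept deviant was itself amplitude-rejected, the
deviant is retained and the standard pool simply shrinks.

## ERP measurement

Averages are re-locked to the deviation onset (offset 250 ms for formal,
0 ms for temporal deviants), with the standard shifted by the *same*
offset as its deviant. On the FCz difference wave, `detect_mmn_peak()`
seeks the most negative local minimum in the primary window (100–300 ms
formal, 200–350 ms temporal) that also satisfies a frontocentral
topography check: the frontocentral ROI mean within ±24 ms must be more
negative than the centroparietal ROI mean. Failing that, the fallback
window (80–300 / 120–370 ms) is searched; as a last resort the global
fallback-window minimum is returned with `qc_flag = TRUE`. This
deterministic rule replaces the visual inspection step of manual
workflows; the QC flag marks exactly the cases a human would have
re-examined. Ties break toward earlier latencies, and latencies live on
the 250 Hz sample grid (4 ms).

Mean amplitudes are taken over ±24 ms (13 samples) around the FCz latency,
separately for standard and deviant, per electrode and for the
frontocentral (Fz, F1–F4, FCz, FC1–FC4) and centroparietal (Cz, C1–C4,
CPz, CP1–CP4) ROIs. Whether FCz's own amplitude belongs in the
frontocentral ROI is ambiguous in manual practice; it is included by
default (the ROI lists include it) with an `include_peak_channel = FALSE`
switch.

## Statistics

All factors are 2-level and within-subject, so every ANOVA effect has one
numerator degree of freedom and reduces to a one-sample t-test on a
per-subject contrast score (±1 cell coding); `rm_anova_2k()` computes
`F = n·mean(score)²/var(score)` with df (1, n−1). This is algebraically
identical to the classical repeated-measures decomposition (verified in
tests against `aov` with subject-error strata to 1e-9), and sphericity
corrections are unnecessary at df = 1. Amplitudes are analysed in a
2×2×2×2 design (PhonProb × SylStr × Condition × ROI) per deviant type;
peak latency, measured once per cell at FCz, in a 2×2 (PhonProb ×
SylStr). Zero-variance contrasts yield flagged degenerate results rather
than errors.

The a priori hypothesis family per deviant type contains five tests —
amplitude: condition main effect, feature × condition, three-way
interaction; latency: feature main effect, PhonProb × SylStr — and Holm's
step-down correction is applied within that family
(`hypothesis_report()`). The original family size is not recoverable from
published descriptions, so m is configurable and always reported next to
the adjusted p-values. Post-hoc paired t-tests are two-sided with
Bonferroni correction across the two ROIs.

## Validation strategy and problem sizes

Published F and p values from the original human data cannot be
reproduced without the recordings; validation instead rests on:

1. **Oracle equivalence** — the contrast-score ANOVA agrees with a
   brute-force GLM oracle to 1e-9 on random 3–24-subject tables, and main
   effects equal squared paired t statistics.
2. **Type-I calibration** — on null cell-mean simulations (n = 24, 1,000
   replicates) each effect's rejection rate at α = 0.05 stays within
   Monte-Carlo error of the nominal level.
3. **Parameter recovery** — the full pipeline, at a reduced problem size,
   recovers an injected −40 ms HPP–LPP latency difference and detects the
   corresponding main effect (Holm-corrected, correct direction) in the
   large majority of seeded replicates.

The scaled profile used for simulation studies (`study_config("scaled")`)
runs 8 subjects, a 16-channel montage (10 scalp channels covering the two
ROI rows, mastoids, 4 EOG, with correspondingly reduced ROI sets), 400
trials per condition (336 standards + 32 deviants per type, divisible by
the 8 separations), 250 Hz synthesis, pink-noise SD 4 µV, and no blinks.
These sizes were fixed once as a realistic "high signal-to-noise,
small-sample" regime for recovery studies; the full-scale profile
(`study_config("full")`) keeps the full design counts, 63 channels and
1000 Hz.

## Numerical conventions

* Half-open epoch and baseline intervals; endpoint-inclusive ±24 ms
  amplitude windows (13 samples at 250 Hz).
* Event samples are 1-based; downsampling maps sample *s* to
  `floor((s−1)/f)+1`.
* Peak ties break toward earlier latency; flat-bottomed dips report their
  earliest sample.
* All stochastic steps (sequence order, tokens, noise, subsampling, ICA
  initialization) are seeded; per-participant and per-condition seeds are
  derived deterministically from the master seed below 2³¹.
* BrainVision export quantizes at 0.1 µV into 16-bit integers; the
  float32 + JSON fallback and the plain-text epoch container are lossless
  to write precision.

## Known limitations

* The noise model lacks spatial correlation, so ROI averaging is somewhat
  more effective here than on real data; recovery rates are upper bounds.
* The automated EOG-correlation rule removes only components that resemble
  the recorded EOG; slow drifts or muscle artifacts are handled only by
  the amplitude criterion.
* Peak-latency estimates on single-subject difference waves remain noisy
  at realistic trial counts; the hypothesis tests inherit that variance,
  as they do in practice.
* The schematic electrode grid supports topography weighting and ROI
  analysis but is not a digitized montage; no source-level analysis is
  attempted.
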