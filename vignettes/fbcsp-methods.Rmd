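---
title: "Filter-bank CSP classification and neurofeedback simulation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filter-bank CSP classification and neurofeedback simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbcsp)
```

This vignette is the package's own account of the science it implements: the
model and its assumptions, the parameters that matter, the numerical choices,
what the synthetic generator does and does not emulate, and the decisions we
made where the design was genuinely open.

## The classification model

The pipeline discriminates two imagery states (by convention "H", happy
emotional imagery, and "M", kinesthetic motor imagery) from multichannel EEG
on a trial-by-trial basis. Its premise is physiological: different imagery
states change the *spatial distribution of band-limited signal variance*
(event-related desynchronization/synchronization), so a classifier should
look at variance ratios of spatially filtered, band-limited signals rather
than at raw amplitudes.

**Filter bank.** Each trial is decomposed into six contiguous 6 Hz bands
covering 0–36 Hz. This spans the delta-to-low-gamma range in which imagery
effects are reported while keeping each band narrow enough that a single CSP
decomposition per band faces an approximately stationary spatial structure.

**CSP.** Within each band, the per-trial sample covariance (after channel
mean removal) is normalized by its trace — so trials with different overall
power contribute equally — and averaged within class, giving `S_A` and
`S_B`. The composite `S_A + S_B` is whitened and the whitened `S_A` is
eigendecomposed; the resulting projection `P` satisfies
`t(P) (S_A + S_B) P = I` with `t(P) S_A P` diagonal. The paired class
eigenvalues sum to one per component — an analytic identity the test suite
asserts to 1e-8 — so components at the top of the spectrum are maximally
class-A-dominant and those at the bottom maximally class-B-dominant. We sort
descending by class A and take the first and last `m` components. Features
are normalized log variances, which are scale-free (the trace normalization
cancels) and approximately Gaussian.

A notational point worth fixing: columns of `P` are spatial *filters*
(applied as `Z = t(P) E`), while columns of `solve(t(P)) = (S_A + S_B) P`
are spatial *patterns*, the scalp projections used for topographic
interpretation and for the similarity analysis. The package stores both.

**Feature selection.** With 6 bands and `2m` components each there are
`12m` candidate feature columns. Each is scored by its mutual information
with the class label, estimated with per-class univariate Gaussian kernel
densities (normal-reference bandwidth `1.06 σ n^{-1/5}`) evaluated at the
training points, Bayes' rule for the class posterior and the sample average
of the posterior entropy. The estimator is clipped to `[0, H(ω)]`; a
constant column scores zero. The `k` best columns are selected
individually, with ties broken deterministically on ascending (band,
filter) order so that a refit reproduces the same model. The classic
filter-bank-CSP variant that also pulls in each selected component's mirror
filter is implemented (`pair_completion = TRUE`) but off by default: we
implement selection exactly as the individual top-`k` rule and leave the
paired variant as an option, since both are defensible and the difference
is measurable only at small `k`.

**Classifier.** A soft-margin linear SVM on the selected features, with
decision function `w·x + b` and objective `½ w·w + C Σ ξ`. Features are
already log-scaled and dimensionless, so no extra standardization is
applied. The sign convention is fixed package-wide: positive decisions mean
class A ("H").

### Default parameters

| parameter | default | meaning / rationale |
|---|---|---|
| bands | 6 × 6 Hz over 0–36 Hz | delta–low-gamma coverage, narrow enough for stationary spatial structure |
| `m` | 2 | CSP components kept per side per band; standard for ~28-channel montages |
| `k` | 4 | selected feature columns; small enough to resist overfitting 80-trial sessions |
| `C` | 1 | SVM slack weight; log-variance features are already scale-stabilized |
| `clip_frac` | 0.015 | outlier fraction clipped per tail before fusion (≈ ±100 µV on adult EEG) |
| `threshold` | 0.75 | individual CV accuracy required to enter the fused model (equality passes) |

## Filter design

Chebyshev type-2 band-pass filters give a flat passband (no ripple on the
signal the covariance sees) with an equiripple stopband. The
specification we adopt: prototype order 8, 30 dB stopband attenuation,
stopband edges 2 Hz outside each band edge, so 6 Hz bands abut without
spectral gaps. Direct polynomial realizations of these filters are
numerically unstable at 500 Hz (relative bandwidths near 1%): measured pole
magnitudes exceed 1. The package therefore designs in zero-pole-gain form —
closed-form analog prototype, band transform, bilinear transform — and
factors the result into cascaded second-order sections (biquads), which the
test suite verifies against the transfer function evaluated on the unit
circle: attenuation is exactly 30 dB at the stopband edges and all poles
lie strictly inside the unit circle.

Two special cases. The 0–6 Hz band cannot be a band-pass (a 0 Hz edge is
ill-posed) and is realized as a 6 Hz low-pass preceded by per-trial DC
removal. And all filtering is *causal* by default, offline and online, so
that offline-trained models see the same filter phase response the online
loop produces; zero-phase forward–backward filtering is available
(`mode = "zero_phase"`) but off by default for exactly that reason.

## Evaluation protocols

`cross_validate()` runs repeated k-fold CV (default 10 × 10) with trials
reshuffled each repetition. Folds are *stratified by class*: with 40 trials
per class, unstratified folds can produce single-class test folds, which
make accuracy undefined for one class. Band-pass filtering and the
per-trial covariance are label-free per-trial operations, so they are
computed once; everything supervised — class covariances, CSP, MI
selection, SVM — is refit inside each training fold only. A test asserts
the per-trial locality that makes this split airtight: the covariance stack
of any subset of trials is identical to the matching slice of the full
stack, so nothing a training fold computes can depend on held-out trials.

`randomization_test()` repeats the CV with uniformly permuted labels to
build a null distribution (the reference protocol uses 1001 repetitions);
the observed accuracy's percentile rank uses strictly-less counting with
ties counted as half, the unbiased empirical convention. On balanced data
the null mean sits at 50% — the acceptance suite requires agreement within
two percentage points over 200 permutations.

`leave_one_subject_out()` trains a fused pipeline on all subjects but one
and tests on the holdout. The held-out subject is normalized with *its own*
pooled amplitude quantiles, because that is what an online system does with
a new user it has never seen; using the training subjects' bounds would
understate transfer performance whenever acquisition gain differs.

## The online loop

The simulated session follows timed block schedules. Offline sessions: five
4-minute runs (224 s of blocks each), eight cycles per run of
cue-image (5 s) → pause (2 s) → H (5 s) → pause → R (5 s) → pause → M (5 s)
→ pause, i.e. 80 regulation trials per session. Online runs: fixation,
four 20 s regulation blocks (H/M alternating) each followed by 10 s rest, a
second fixation, then four more regulation blocks — 280 s per run, eight
regulation blocks, 32 regulation trials per session of four runs, 96 over
three sessions. The protocol's nominal "5-minute run" is consistent with
this arithmetic only up to rest-block placement; we fix the symmetric
layout above and document the 280 s span rather than forcing a round
number.

Classification consumes the last 1 s of data (500 samples at 500 Hz) every
second during regulation blocks. Filtering is causal and continuous across
each run with state reset at run start. The SVM bias — sensitive to cap
placement, impedance and the subject's state — is re-estimated as the mean
raw decision value over each fixation block's windows and subtracted from
subsequent decisions; the mid-run fixation exists precisely so the second
half of the run gets a fresh estimate. Baseline windows are the same 1 s
length as feedback windows, keeping the bias estimate on the same scale as
the decisions it corrects.

`run_accuracy()` discards the first window of each regulation block (the
filter transient plus imagery-onset lag) and scores the rest: with the
default protocol that is 8 × 19 = 152 scored windows per run. The burn-in
count is configurable; one window is our reading of why a 160-window run
scores 152 labels, documented as an assumption rather than asserted as
mechanism.

The thermometer moves one bar per update, upward when the decision sign
matches the cued class. Since participants are instructed to drive the bar
*up* under both cues, the only consistent reading is cue-relative sign
(positive-under-H, negative-under-M); a raw-sign mode
(`cue_aware = FALSE`) is available for the literal alternative.

## The synthetic generator

`generate_subject()` builds trials as `mixing %*% sources + noise`: six
band-limited unit-variance Gaussian sources (one per analysis band,
produced by the package's own band filters so generated spectra align
exactly with the analysis bands), mixed through smooth Gaussian spatial
profiles, plus white sensor noise (default 10 µV). Class structure is a
variance ratio on designated sources: by default a frontal 6–12 Hz source
is 4× stronger in variance during "H" and a central 18–24 Hz source 4×
stronger during "M" — the frontal-versus-central contrast the classifier is
meant to exploit, at a deliberately strong effect size (real inter-class
ratios are closer to 1.2–2) so that test failures indicate implementation
faults rather than noise. A per-subject jitter on the mixing columns
(`subject_jitter_sd`) creates families of related subjects for fusion and
transfer tests. `generate_online_stream()` runs the sources continuously
over a schedule and applies the cued class's gain per 1 s window with
probability `compliance`.

What the generator does *not* emulate, and what passing tests therefore do
not show: ocular/muscle artifacts and electrode drift, nonstationarity
within and across sessions, volume-conduction realism (profiles are
positional, not montage-based — the channel montage is treated as opaque
throughout), 1/f background spectra, and genuine inter-individual
variability beyond mixing jitter. Results on real recordings will be
noisier in every respect; the generator's role is ground-truth validation
of the machinery, not performance forecasting.

## Numerical choices and degenerate inputs

- **Covariance shrinkage**: if the composite covariance's condition number
  exceeds 1e10, both class covariances get
  `S ← (1−γ)S + γ (tr S / C) I` with `γ = 1e-6`, with a warning. Normal
  28-channel, 2500-sample trials never trigger this; degenerate synthetic
  edge cases must not crash.
- **Variance floor**: projected rows with zero variance are floored at
  1e-12 before the log, with a warning.
- **MI degeneracies**: constant feature columns score 0; the kernel
  bandwidth falls back to a tiny positive value for near-constant classes;
  densities are floored at the smallest positive double before Bayes
  inversion.
- **Ties**: feature selection breaks MI ties on ascending (band, filter);
  permutation ranks count ties as half.
- **Event timing**: onsets/durations are seconds, converted to samples by
  half-up rounding; trials are half-open sample windows, so adjacent blocks
  never share a sample.
- **Seeds**: every randomized stage derives its own substream from the
  global seed via `sub_seed()` (a fixed integer hash kept below 2^31), so
  adding a stage never perturbs earlier stages' draws.

## Problem sizes in the test suite

Unit tests run on reduced configurations (typically 12 channels, 2 s
trials, 20–30 trials) chosen to exercise every code path quickly; the
acceptance tests run the properties that depend on scale — eigenvalue
pairing on 28×28 covariances, chance-level calibration on 80 trials over
200 permutations, parameter recovery and the closed online loop at 28
channels / 500 Hz — at the study's native scale. The full suite completes
in a few minutes on one CPU.

## Known limitations

Binary classification only (the two-class alphabet is structural, not a
placeholder for multi-class CSP). No artifact handling: recordings are
assumed cleaned upstream. The EDF reader supports the common
equal-rate-signals EDF/EDF+C layout, not discontinuous EDF+D. CSP
similarity indices are reported as defined (absolute values, 0–1 scaling,
per-condition comparison of the most prominent patterns), but their
interpretive value is limited — patterns reflect *discriminative* structure
and legitimately change when either class's state changes, which is why
classification accuracy, not pattern similarity, is the primary performance
measure.
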