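---
title: "Closed-loop fNIRS neurofeedback: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop fNIRS neurofeedback: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfnirs)
```

This vignette is the package's own account of what it computes and
why. It covers the processing model of the online feedback chain, the
offline quality-control and robustness analyses, the success metrics,
the behavioural pipeline, and — since every stage is validated against
simulated data — what the synthetic generator does and does not
emulate. Points where the protocol under-determines the computation
are collected at the end, together with the numerical choices made
there.

## The closed-loop processing model

A training comprises 12 runs over four days (2, 4, 4, 2); each run
has six blocks of: a no-regulation period (25 s or 30 s, jittered), a
30 s regulation period, and a 2 s reward display. Recordings are
two-chromophore (HbO/HbR) series at 10 Hz from a 2 × 22-channel
bitemporal montage; one right-hemisphere channel over the rTPJ drives
the feedback.

`run_closed_loop()` replays the online computation exactly as a
streaming system would execute it, 100 ms per step:

1. **Device filtering** (`device_preprocess()`): causal 2nd-order
   Butterworth high-pass at 0.01 Hz and low-pass at 1 Hz, then a
   causal 5 s moving average. Causality matters: a real-time system
   cannot use zero-phase filtering, and the causal chain's phase lag
   is part of what the participant actually saw. (Zero-phase variants
   exist for offline work, see below.)
2. **Per-trial CBSI** (`estimate_trial_params()`, `cbsi_correct()`):
   from the last 30 s of the preceding no-regulation period (or the
   full period when it is the 25 s variant — the stated 30 s window
   cannot fit there), the HbO/HbR means give the offsets and
   `alpha = sd(HbO)/sd(HbR)` the noise-amplitude ratio; during
   regulation each offset-corrected sample pair becomes
   `(x − alpha*y)/2`. CBSI rests on two assumptions: neural HbO and
   HbR are strongly anticorrelated, while motion moves both together.
   When HbR exactly mirrors HbO (`y = −x/alpha`) the correction
   returns `x` unchanged; a shared spike is attenuated.
3. **Baseline normalisation** (`normalize_feedback()`): the corrected
   value is centred on the median of the last 5 s of no-regulation
   HbO and divided by that window's standard deviation.
4. **Display smoothing** (`smooth_feedback()`): the displayed value
   ramps toward each new target over 1 s (per 100 ms update it covers
   one tenth of the remaining distance). A constant input is a fixed
   point, and the smoother never amplifies total variation.
5. **Mapping and reward** (`map_feedback()`, `accrue_reward()`):
   `10·signal/(k·T)`, negated for downregulation, clamped to [0, 10];
   the avatar image index is the round-half-up integer (11 images,
   levels 0–10); reward is earned strictly above level 5 at 0.01 EUR/s
   (at most 0.30 EUR per 30 s trial, 21.60 EUR per training).
6. **Threshold adaptation** (`adapt_k()`, between runs): if the
   feedback value exceeded level 5 for at least 75% of the run's
   regulation time, pooled over its six trials, `k` grows by 0.25.

The individual threshold `T` (`initial_threshold()`) is the mean of
two pre-assessment activation contrasts (invalid − valid cueing;
perspective − no-perspective taking); a non-positive mean falls back
to the positive contrast alone, and if both contrasts are negative to
the default `T = 1`.

### Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| sample rate | 10 | Hz | device export rate; all window lengths derive from it |
| `k0` | 0.25 | fraction of `T` | level 10 = 25% of the threshold at training start |
| k step | 0.25 | — | difficulty increment per sufficiently successful run |
| reward level | 5 | display levels | strict `> 5` comparison |
| reward rate | 0.01 | EUR/s | 1 cent per second above level |
| alpha window | 30 (or 25) | s | pre-trial noise-ratio estimation |
| baseline window | 5 | s | normalisation statistics |
| smoothing ramp | 1 | s | display inertia |
| `md` | median | — | baseline centring statistic (mean available) |

## Offline QC and robustness

Channel screening (`detect_bad_channels()`) excludes a channel when
CoV exceeds 10% in either chromophore, when the chromophore CoV
difference exceeds 5 points, or when either series contains ≥ 1 s of
bitwise-identical samples (10 at 10 Hz; exact identity, because
device quantisation makes exact repeats the meaningful signature of a
dead channel). CoV is `100·sd/|mean|` and needs the series' DC level:
the screening therefore operates on the raw device export, not on
high-passed data, and channels whose |mean| is numerically zero are
routed to a manual-review flag rather than auto-excluded. A flagged
feedback channel can be re-included after visual inspection
(`reinclude_channel()`), which requires a non-empty justification and
keeps an audit log.

Unusable trials are replaced by the sample-wise mean of up to six
neighbouring trials, three on each side, truncated at the sequence
edges (`interpolate_bad_trials()`). Within-trial outliers beyond 3 SD
of the trial mean — mean and SD computed once, on the original trial —
are replaced by the last retained observation, a leading outlier by
the next retained one (`remove_outlier_samples()`).

`offline_reanalysis()` recomputes per-trial medians and SDs of the
feedback signal under three variants: `replication` (the online chain
unchanged — it shares the trial-wise internals with the engine, so
agreement is exact by construction), `robust1` (inserting a
zero-phase 3rd-order Butterworth band-pass, 0.01–0.09 Hz, implemented
as a high-pass/low-pass cascade because a single narrow band-pass at
these corners is numerically fragile), and `robust2` (subtracting the
mean of the 22 left-hemisphere channels from the feedback channel,
per chromophore, before CBSI). The band-pass removes cardiac (~1 Hz),
respiratory (~0.3 Hz) and Mayer-wave (~0.1 Hz) components; CAR
removes whatever is common across the montage, at the known risk of
over-correction when task activity is bilateral.

## Success metrics

A run is successful when the median of its six trial medians is
strictly positive (upregulation) or strictly negative
(downregulation); an exact zero is unsuccessful. A participant is
classified successful with more than 50% successful runs (≥ 7 of 12).
Improvement is measured twice: as the unweighted OLS slope of the run
means over run index 1–12, and as the last-vs-first session
difference, mean(runs 11, 12) − mean(runs 1, 2); both are
sign-matched to the trained direction. The same two statistics on the
run means of the trial SDs quantify variability change, where a
decrease counts as learning in both groups. Group-level inference
uses one-sample and paired t-tests with Cohen's d, Welch correction
for independent comparisons, and Bonferroni-corrected Spearman
correlations for associations.

`sensitivity_min_effect()` inverts the power function of the
independent-samples t-test by bisection on Cohen's d, using the
noncentral t distribution with noncentrality
`d·sqrt(n1·n2/(n1+n2))`. For groups of 27 and 18 at one-sided
alpha = 0.05 and 80% power it returns d = 0.769 (0.77 at two
decimals). Sidedness is exposed because designs differ; one-sided is
the default for directional regulation hypotheses.

## Behavioural pipeline

Attention-task analysis keeps correct trials with
100 ≤ RT ≤ 1000 ms — the printed limits "< 100" and "> 1000" are
strict, so the boundary values survive. Central tendency uses the
harmonic mean, which down-weights slow outliers while retaining
power. The reorienting cost is HM(invalid) − HM(valid) from invalid
blocks only; the positive sign convention (cost) is used throughout.
vPT summaries are per participant × time × condition accuracies and
harmonic-mean RTs over all trials; no RT window is applied there, and
perfect accuracy raises a ceiling flag. `prepost_effects()` first
aggregates per participant, then computes group × time cells, paired
within-group changes with d = mean(Δ)/sd(Δ), and a Welch t-test on
the changes between groups.

## What the synthetic generator emulates

`simulate_recording()` produces, per channel: a neural response (30 s
regulation boxcar convolved with a peak-normalised double-gamma HRF —
peak near 6 s, undershoot near 16 s — scaled by that run's regulation
amplitude, non-zero only on the feedback channel), shared systemic
physiology (sinusoids at 1.1, 0.3 and 0.1 Hz with per-participant
random phases; default amplitudes 0.2, 0.3, 0.5 signal units), a
linear drift (0.1 units/min), a device-export DC level (10 units),
and independent white noise (SD 0.1). Neural HbR is exactly
`−0.5 ×` neural HbO, so the neural components correlate at −1 by
construction before noise. Artifacts (motion spikes moving both
chromophores together, flat lines, high-variance segments) are
injected on demand. The cardiac default is 1.1 Hz — a typical resting
heart rate of 66 bpm — rather than a textbook 1.0 Hz, which at 10 Hz
sampling coincides with a transmission null of the 5 s moving average
and would therefore vanish from every analysis variant at once.

The default amplitude trajectories encode the two canonical training
outcomes: constant positive across all 12 runs for upregulation, and
a linear decline from +1 to −1 for downregulation. No published
magnitude exists for single-channel rTPJ responses in these units;
the defaults were chosen once so that success and failure scenarios
are cleanly separable by the analysis chain, and they are not
physiological calibrations.

`simulate_behavior()` draws trial RTs from a shifted lognormal
(shift 150 ms, moment-matched per design cell) and correctness from
per-cell accuracy rates. Default cells reproduce the studied
population's baselines per condition; post-assessment cells shift by
the across-condition group changes (−17 ms up, +15 ms down for the
attention task; about −130 ms and +2.5 accuracy points for vPT). The
Posner layout is exact: 12 blocks, 6 invalid blocks of 12 valid + 8
invalid trials, 6 valid blocks of 20 valid trials. The vPT task uses
4 trials per block and, absent a stated block count, 4 blocks per
condition.

**What it does not emulate.** Simulation starts at chromophore
concentrations — no optics, no modified Beer–Lambert forward model,
no photon-migration anatomy. Physiology is stationary sinusoids, not
the amplitude- and frequency-wandering rhythms of real recordings;
noise is white, whereas real fNIRS noise is coloured; there is no
between-participant variance in the behavioural generator beyond
sampling noise (cell parameters are population constants). Passing
tests therefore demonstrate that the *computations* are correct and
that the pipeline recovers known ground truth under realistic
block-design conditions — not that the defaults reproduce any
particular human dataset.

## Numerical choices and degenerate inputs

- "md" in the baseline formula is read as the **median** of the 5 s
  window; the mean is available via `md = "mean"`.
- Degenerate windows: a zero-variance HbR window sets `alpha = 1`
  with a flag; a zero-variance baseline substitutes a machine-epsilon
  guard, also flagged. Both keep the stream finite without inventing
  signal.
- Clamping to [0, 10] defines behaviour outside the display scale;
  image quantisation is round-half-up.
- The reward comparison is strict (`> 5`); the k-adaptation boundary
  is inclusive (`≥ 75%`), pooled over the run's regulation samples.
- A run-success median of exactly 0 counts as unsuccessful (strict
  signs); with 12 runs, "> 50%" means ≥ 7.
- `initial_threshold()` treats a zero contrast mean like the negative
  case (fall back to the positive contrast, else 1), since `T` must
  be positive.
- The causal high-pass is referenced to the first sample, and the
  moving average uses an expanding mean during its 5 s warm-up, so a
  constant-start series produces no spurious onset transient.
- Filter problem sizes in the test-suite simulations follow the
  protocol (full 12-run trainings, ≈ 43,000 samples); bulk
  parameter-recovery studies simulate only the feedback-channel pair
  (`n_channels = 2`), which is exact because the online chain reads
  no other channel, and run 20 participants per cohort with 100
  replicate cohorts for null-calibration checks.

## Known limitations

- SNIRF interchange is not implemented; the canonical format is the
  TSV dialect documented in `write_recording_tsv()`.
- Linear mixed models, nonparametric ANOVA-type statistics, and
  stepwise predictor models are out of scope; the t-test/Cohen's
  d/Spearman family stands in for group-level inference.
- The online replication of the offline variant shares code with the
  engine, so their agreement is a consistency property, not an
  independent cross-validation; the independent checks live in the
  test suite's closed-form and brute-force oracles.
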