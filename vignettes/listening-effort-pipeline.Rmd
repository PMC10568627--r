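---
title: "Modelling listening effort from event-related pupillometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling listening effort from event-related pupillometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(pupilgca)
library(dplyr)
```

## The problem

When listeners understand speech in noise, how hard they have to work is not
captured by intelligibility scores alone: two speech styles can be equally
intelligible while one demands far more cognitive effort. The pupil provides
a window on that effort — it dilates more when listening is harder. This
package implements a complete analysis pipeline for speech-in-noise
pupillometry experiments in which listeners hear blocks of masked sentences
(one block per speech style x SNR combination, block order balanced with a
Latin square), report the sentence back (scored against 5 keywords), and
rate each block's effort on a 0-10 scale, while an eye tracker records
pupil size on each trial.

The pipeline covers: a synthetic-experiment generator with known ground
truth; trace I/O in a neutral epoch CSV dialect; the calibration chain from
raw samples to event-related pupil dilation (ERPD); trial and participant
exclusion rules; behavioral statistics (rationalized arcsine units,
repeated-measures correlation); and growth curve analysis (GCA) of the ERPD
time course with linear mixed-effects models.

## The ERPD calibration chain

Each trial's raw recording spans from 2 s before sentence onset (the masker
lead) to 3 s after sentence offset. The chain, in order:

1. **Downsample** to 50 Hz by non-overlapping block means. A block with
   fewer than half of its samples valid becomes missing.
2. **Area to diameter.** Trackers that report pupil area (black-pixel
   counts) are converted by the circular map \(d = 2\sqrt{a/\pi}\). The
   constant is irrelevant: ERPD is scale-free (verified to 1e-10 by a
   property test), which is also why area-based and millimeter-based
   recordings can be analyzed identically.
3. **Artifact detection.** Per trial, samples more than 2 SD *below* the
   trial mean are marked missing — blinks and partial occlusions shrink the
   apparent pupil. The detector is single-pass: mean and SD come from the
   pre-detection valid samples and are not re-estimated, so two
   implementations cannot silently disagree through different iteration
   counts. The trial (not the session) is the statistical unit here, since
   pupil level drifts across a session.
4. **Interpolation.** Each maximal missing run is filled by a least-squares
   line fitted to the valid samples within a window from 5 samples before
   the run to 8 after it. For an isolated missing sample this reduces to the
   classical single-sample rule; treating the run as the unit is what blinks
   require. Runs touching the trace edge with no valid support on one side
   are filled by nearest-value extension and flagged. Observed samples are
   never altered.
5. **Baseline** = mean interpolated diameter over the half-open second
   \([-1, 0)\) before onset (50 samples at 50 Hz).
6. **ERPD** \(= (observation - baseline)/baseline \times 100\), restricted
   to the analysis window 0 to 4.5 s after onset (226 grid points).
7. **Smoothing** with a 5-point centered moving average, truncated
   symmetrically at the edges so the grid length is preserved and constant
   traces pass through unchanged.

Two ordering questions the chain's description leaves open were resolved as
follows: the baseline is computed *after* interpolation (cleaning precedes
the normalization formula), and the QC missing fraction is computed *before*
interpolation over the union of the baseline and analysis windows —
post-interpolation fractions would be identically ~0 and the 15% exclusion
rule vacuous.

```{r chain}
sim <- simulate_experiment(synth_config(
  n_participants = 4, trials_per_block = 5, familiarization_per_block = 0,
  snrs = c(-1, -5), seed = 7
))
pp <- preprocess_trials(sim$traces)
select(pp, participant_id, block_id, trial_index, baseline,
       missing_frac, usable) |> head()
```

## Exclusion rules

Trials are excluded, with exactly one primary reason each (first rule hit):
unusable trace (the automatable stand-in for trials an analyst would reject
on visual inspection), missing fraction strictly greater than 15%, or zero
keywords correct — pupil dilation is uninformative at the intelligibility
floor. Participants retaining strictly less than 80% valid scorable trials
are removed entirely. Both thresholds are strict inequalities, so 15.0%
missing and exactly 80% valid are retained. Zero-correct exclusion applies
to pupil analyses only; intelligibility means keep all scorable trials,
since removing zeros would bias scores upward.

## Behavioral statistics

Intelligibility is scored as keywords correct out of 5 per sentence,
aggregated to participant x speech-type x SNR cells, and converted to
rationalized arcsine units,
\(\theta = \arcsin\sqrt{x/(n+1)} + \arcsin\sqrt{(x+1)/(n+1)}\),
\(RAU = (146/\pi)\theta - 23\), which stabilizes variance near floor and
ceiling. Cell-level (not trial-level) proportions are transformed, because
the percentages being analyzed exist at the cell level. Cell scores are
modelled with SNR and speech type as crossed categorical fixed effects and
a random per-participant intercept; the interaction is tested primarily by
a likelihood-ratio test between ML fits, with the F statistic reported
descriptively using a containment denominator df
\(N - p - k + 1\) — the exact denominator convention used in the original
analyses of such designs is not recoverable, so a simple documented rule is
preferred over emulating an unknown approximation. Pairwise speech-type
contrasts within each SNR use estimated marginal means with Tukey
adjustment and asymptotic (z) degrees of freedom, consistent with the
package-wide normal-approximation inference.

The association between intelligibility and subjective effort is estimated
with the repeated-measures correlation: an ANCOVA with a common slope and
per-participant intercepts, \(r = \mathrm{sign}(b)\sqrt{SS_x/(SS_x +
SS_{err})}\), df \(= N - k - 1\), p from the t distribution (matching the
ANCOVA derivation of the method). It measures the within-listener
association and is invariant to per-participant shifts of either variable.

## Growth curve analysis

The ERPD time course on \([0, 4.5]\) s is modelled with a cubic orthogonal
polynomial basis evaluated on the realized grid: `t0` is the intercept,
`t1`-`t3` are orthonormal and zero-sum, signed to correlate positively with
\(t, t^2, t^3\). The coefficients then read as: mean dilation (intercept),
rate of dilation (linear), peak shape (quadratic), falling slope (cubic).

The full model per SNR is

```
erpd ~ (t1+t2+t3)*speech_type + (t1+t2+t3|participant_id)
```

Trials are first averaged to one curve per participant x speech type:
random effects are per-participant only, so trial-level rows would
pseudo-replicate the fixed effects. The reference level is plain (natural,
unmodified) speech, the baseline every other style is compared against.
Coefficient tests treat t as z; model comparisons use the likelihood ratio,
\(\chi^2\) on the number of parameters added. ML is used for all LRT
comparisons (fixed-effect LRTs are invalid under REML) and REML for the
reported final estimates.

**Model selection** starts from the complete model (all candidate
covariates — e.g. intelligibility — crossed with the polynomial terms) and
drops, least-significant first, every covariate whose removal is not
rejected at \(\alpha = 0.05\). **Non-convergence** is never silent: a
rank-deficient fixed-effect design is detected by a QR rank check before
fitting, optimizer failures are retried from three deterministic perturbed
starts, and if the model still fails, a fallback ladder drops the highest
remaining polynomial x speech-type interaction and refits — full cubic
model, then without `t3:speech_type`, then without `t2:speech_type` — with
every step recorded. The first fallback step yields exactly the reduced
shape

```
erpd ~ (t1+t2+t3) + speech_type + t1:speech_type + t2:speech_type + (t1+t2+t3|participant_id)
```

```{r gca}
el <- erpd_long(pp)
sel <- select_model(filter(el, snr_db == -1))
sel$formula
tidy(sel$fit) |> head(8)
```

## The synthetic-experiment generator

No public raw data exist for this experimental paradigm, so the generator
is a first-class module: every downstream stage is tested against its known
truth. It emulates the block design (one block per speech type x SNR,
cyclic Latin-square order, 15 scored trials preceded by 5 familiarization
sentences per block), the trial timeline (masker from 2 s before onset to
3 s after offset), and the measurement process:

- the raw trace is `baseline * (1 + ERPD(t)/100)`, with the participant
  baseline level drawn from N(1000, 150) arbitrary units;
- `ERPD(t)` is 0 before onset (the baseline window must be stationary for
  the normalization to be recoverable), a condition-specific cubic curve on
  the orthonormal basis over \([0, 4.5]\) s, and held at its end value to
  the trial end;
- participant random effects on all four curve coefficients
  (covariance `diag(4, 4, 2, 1)` by default);
- AR(1) sample noise (marginal SD 1.5% ERPD, coefficient 0.6) rather than
  white noise — real pupil traces are strongly autocorrelated and the GCA
  inference should be exercised under dependence;
- blinks at 2 per trial: a 2-3-sample partial-occlusion dip to 40-70% of
  the local level, then a missing run with exponential mean 0.2 s, placed
  fully inside the trial — the dip gives the 2-SD detector a real downward
  excursion to catch beyond the sentinel values;
- sentence durations jittered ±10% (sentence materials vary in length; the
  pipeline must not assume a fixed trial length);
- keyword scores Binomial(5, p) with logistic psychometric functions of SNR
  per speech style (enhanced styles have lower midpoints, synthetic speech
  the highest);
- block effort ratings `round(clip(10 * (1 - p) + noise, 0, 10))` — a
  deterministic inverse-intelligibility link plus Gaussian rating noise
  (SD 1), so the generator can reproduce the negative
  intelligibility-effort association.

Default curve heights order the speech styles Lombard < SSDRC < plain <
TTS in mean dilation, reflecting that intelligibility-enhancing
modifications reduce listening effort while synthetic speech increases it.
Magnitudes (~6-10% mean ERPD) are typical of speech-in-noise pupillometry.

What the generator does **not** emulate: luminance and the pupil light
reflex, gaze position and foreshortening, head motion, session-scale drift,
or any audio. Passing tests therefore demonstrate correctness of the
computation chain under a plausible measurement model, not robustness to
every artifact of real recordings.

```{r truth}
sim$truth$fixed_effects
```

## Numerical and design choices

- Identical configurations reproduce byte-identical datasets; the
  generator's seed is the only source of randomness, and fitting uses no
  RNG (optimizer restarts perturb parameters deterministically).
- Trace CSVs store floating samples with `%.17g` formatting and are parsed
  through R's `strtod`, so write/read/write is byte-idempotent.
- The missing sentinel is a header-declared value (default: empty field),
  never 0 — zero is a legal area reading during a partial blink.
- LRT calibration simulations use white noise: under AR(1) dependence the
  chi-square reference is not expected to hold exactly, so calibration is
  checked under the model-consistent null. Parameter-recovery simulations
  keep 50 Hz AR(1) noise but fit on a decorrelating 23-point subsample of
  the grid (adjacent-sample correlation 0.006), making the iid-residual
  assumption of the mixed model hold to good approximation.
- Simulation study sizes: 50 replicates at the 24-participant experiment
  scale for coefficient recovery, 200 replicates at 16 participants for
  null calibration of the speech-type LRT — sizes chosen so each study
  runs in minutes while keeping Monte-Carlo error well inside the margins
  being tested.
- Degenerate inputs: a constant behavioral response yields F = 0 and LRT
  p = 1 rather than 0/0; empty design cells, non-PSD covariances, and
  sub-baseline trial spans are rejected with explicit messages.

## Known limitations

- The behavioral F denominator df is a documented convention, not an
  attempt to reproduce any particular software's approximation; LRT
  p-values are the primary inference.
- Keyword scoring credits case-folded exact matches only; morphological
  variants ("plank"/"planks") are not credited.
- The fallback ladder order (drop `t3:speech_type`, then `t2:speech_type`)
  is a deterministic convention extending the single documented reduction.
- Vendor formats (EyeLink EDF, Tobii) are out of scope; recordings must be
  epoched to the documented CSV dialect first.
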