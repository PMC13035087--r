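---
title: "From raw light intensities to group inference: the nirspipe model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw light intensities to group inference: the nirspipe model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package models

`nirspipe` analyses prefrontal functional near-infrared spectroscopy (fNIRS)
recordings acquired with an 8-channel, dual-wavelength (760/850 nm) optical
topography montage sampled at 10 Hz, during a block-design session with four
conditions: movement-evoked pain on the noninjured and the injured side
(hold–move–hold cycles whose 5-s holds form the labelled blocks), and two
6-minute immersive VR blocks (relaxation, then distraction). The montage
covers four prefrontal regions with two channels each: right lateral
(channels 1–2), right medial (3–4), left medial (5–6) and left lateral
(7–8).

The pipeline produces three subject-level measures per condition —
GLM activation betas, prestimulus-baseline Cohen *d*, and pairwise channel
coactivation — and then paired pre/post group inference with
Benjamini–Hochberg correction, brain–behaviour correlations against a
battery of pain and coping instruments, and sensitivity analyses.

A synthetic-data generator produces raw recordings with the same statistical
structure, with every planted quantity exported, so each stage can be tested
against ground truth without any proprietary acquisition file.

## Signal model

### Optical density

Raw intensities are converted per channel and wavelength to optical density
change

$$\mathrm{OD}(c,\lambda,t) = -\ln\!\frac{I(c,\lambda,t)}{\overline{I}(c,\lambda)},$$

normalised by the trace's time mean. The natural log and the mean
normalisation follow the convention of the standard conversion used in fNIRS
toolboxes; OD is scale-free in the source intensity, which is why the
simulator's arbitrary baseline intensity of 1.0 is unobservable downstream.

### Motion artifacts

Brief motion transients are flagged on OD with a sliding window of
`t_motion = 0.5` s: a window is flagged when its amplitude excursion
(max − min) strictly exceeds `amp_thresh = 0.1` OD units, or when the
standard deviation of its sample-to-sample differences strictly exceeds
`sd_thresh = 5` times the record-wide SD of those differences. Flags are
dilated by `t_mask = 1` s on each side and combined across the two
wavelengths of a channel. Both criteria use strict inequalities, so a step
of exactly 0.1 OD is not flagged; the boundary is pinned by tests against a
brute-force window scan. Flagged samples are **masked, not repaired** — no
spline or wavelet correction is applied — and the mask excludes those
samples from every downstream estimate (GLM, Cohen *d*, coactivation).
Manual pre-marked exclusion spans are merged into the same mask.
The mask is monotone in both thresholds: lowering either never shrinks it.

### Band-pass filtering

A third-order Butterworth band-pass with corners at 0.01 and 0.2 Hz removes
slow drift and cardiac/respiratory oscillations while retaining the
hemodynamic response. It is applied forward–backward (zero phase), the
dominant fNIRS convention, so block timing is not shifted. All data are
filtered and the motion mask is carried through unchanged; the ambiguity of
whether only motion-affected stretches should be filtered is resolved in
favour of uniform filtering with the mask retained. Filtering operates on
OD before the Beer–Lambert inversion; because that inversion is linear, the
order is immaterial, which a test asserts indirectly through exact
round-trip recovery.

### Modified Beer–Lambert law

Per channel and sample the 2×2 linear system

$$\Delta \mathrm{OD}(\lambda) = \left[\varepsilon_{\mathrm{HbO}}(\lambda)\,\Delta\mathrm{HbO} + \varepsilon_{\mathrm{HbR}}(\lambda)\,\Delta\mathrm{HbR}\right] L\,\mathrm{DPF}(\lambda)$$

is solved for (ΔHbO, ΔHbR), with extinction coefficients in
cm⁻¹ mM⁻¹ (Gratzer/Cope compilation: 0.5864/1.5485 at 760 nm,
1.0580/0.6916 at 850 nm), source–detector separation `L = 3.5` cm (typical
of this montage geometry; configurable, and all round-trip tests reuse the
configured value so correctness does not depend on it), and an age- and
wavelength-dependent differential pathlength factor in the general
Scholkmann–Wolf form

$$\mathrm{DPF}(a,\lambda) = \alpha + \beta a^{\gamma} + \delta\lambda^{3} + \epsilon\lambda^{2} + \zeta\lambda .$$

Over the cohort's plausible adult age range this formula gives roughly
5.9–7.0 at 760 nm and 5.1–6.1 at 850 nm. Acquisition reports for this
class of device often quote a DPF interval near 6.0–6.6 derived from
age-only formulas at a single reference wavelength; the two
parameterisations are not identical, and the package pins the
two-wavelength form (coefficients in configuration) because the inversion
needs a value per wavelength. All round-trip tests are formula-agnostic by
construction: the simulator and the pipeline share one configuration.

## Subject-level measures

### GLM activation

Each condition's regressor is its block boxcar (half-open intervals
`[onset, onset + duration)`) convolved with a canonical double-gamma HRF
(peak 6 s, undershoot 16 s, undershoot ratio 1/6, kernel support 32 s,
peak-normalised so betas keep µM units). Nuisance columns are an intercept
and a linear drift. Ordinary least squares is fit per channel on HbO only —
HbR is computed and stored but not analysed, reflecting the higher
signal-to-noise of HbO — restricted to mask-valid samples; starved or
rank-deficient channels yield `NA` with a warning, never an error.

When the data have been band-pass filtered, the condition and drift
regressors are filtered with the identical zero-phase filter, and one extra
column — the filtered constant — is appended. This matters: the OD
definition leaves each channel an arbitrary constant offset, and a
zero-phase band-pass turns a constant into a small edge transient. With the
filtered design the model spans that transient exactly, which is what makes
noiseless forward-model recovery exact to numerical precision (the test
bound is 10⁻⁶ µM; the observed error is ~10⁻⁸) instead of biased at the
filter edges. The switch `filter_design` exposes this choice.

### Prestimulus-baseline Cohen *d*

For each condition, *d* is the difference between the mean HbO over the
condition's samples and the mean over the 10 s immediately preceding the
condition's first block, divided by the pooled SD of the two intervals.
The source description defines the numerator but not the denominator;
pooled SD follows common effect-size usage in prior fNIRS work, and a
baseline-only denominator is available behind `d_denominator` for
literal replication. The baseline length is configurable
(`baseline_window_s`). Increased HbO during the condition gives *d* > 0,
matching the sign convention of reported channel-level increases.

### Pairwise coactivation

Pearson correlations of HbO between all 28 unordered channel pairs,
computed within the condition's span only (state-related, not whole-record),
using jointly valid samples. Pairs are indexed lexicographically:
FC1 = (1,2), …, FC7 = (1,8), FC8 = (2,3), …, FC28 = (7,8). No published
definition of this numbering exists to our knowledge; the lexicographic
reconstruction is adopted because, together with the channel-to-region map
above, it reproduces every printed pair label we anchor to — FC3
(right lateral–right medial), FC4 (right lateral–left medial), FC18 and
FC21 (right medial–left lateral), FC23 (within left medial) — and a
structural test locks all five equivalences. Region-pair summaries average
the four inter-region channel-pair correlations (or take the single
intra-region pair).

## Group-level inference

Paired *t*-tests on post − pre values with pairwise deletion of incomplete
subjects: MD = mean difference, `t = MD / (SD(diff)/√n)`, two-sided *p*
with df = n − 1, and paired `d = MD / SD(diff)` (the identity
`d = t/√n` holds on every output row and is asserted). Coactivation values
are Fisher z-transformed before the *t*-test — the standard choice for
inference on correlations — with the mean difference reported back on the
*r* scale; a `fisher_z = FALSE` switch retains the raw-*r* pathway.
Benjamini–Hochberg correction is applied within families: the 8 channels of
one condition and metric, the 28 pairs of one condition, and the behavioural
battery as one family. Family boundaries are not stated in the source
material; these are the natural per-test-table groupings. Both *p* and *q*
are always reported. The feasibility ledger counts scheduled recordings
(subject × visit × condition) as valid/missing/invalid and rounds the valid
percentage half-up, so 74/80 = 92.5% prints as 93%.

Sensitivity analyses: Spearman correlations of time-since-injury with
baseline and change scores (BH-corrected as one family), leave-one-out
re-estimation of every paired test reporting the *t* range across folds,
and ANCOVA (OLS of post on baseline + time-since-injury + collapsed injury
type) reporting covariate coefficients and *p*-values; constant covariates
are dropped with a warning. A robust-regression variant is deliberately not
implemented (estimator unspecified in the source description).

## The synthetic cohort generator

The generator is the package's testing instrument, and its defaults are the
study conditions:

* **Design**: the full session protocol — 10 hold–move–hold cycles per side
  (move 2.5 s, hold 5 s, relax 3 s; two labelled 5-s holds per cycle, so 20
  holds per side), then the two 360-s VR blocks, with rest periods of
  30/120/60 s providing prestimulus baselines.
* **Cohort**: n = 10 subjects, 2 visits, 4 conditions; ages ~ N(47, 12²)
  truncated to [18, 80]; time-since-injury ~ N(38.4, 36.3²) days, injury
  type 90% fracture — all mirroring the published cohort table.
* **Neural truth**: per-channel, per-condition betas (movement 0.2–0.35 µM,
  VR 0.15–0.25 µM — ordinary magnitudes for prefrontal block designs);
  between-subject beta SD 0.05 µM and within-subject pre-to-post change SD
  0.05 µM. The planted treatment effect adds 1.5 × change-SD to channel 4
  in both VR conditions. The multiple 1.5 was fixed from the power of the
  paired *t*-test at n = 10 (≈ 0.80 at exactly 1 SD — a knife edge for a
  regression guard — versus ≈ 0.97 at 1.5 SD) before any test was run, and
  is not revisited.
* **Coactivation truth**: band-limited (0.02–0.1 Hz) unit-SD shared signals
  added to channel sets (4,7) and (3,8) with weights 0.3 and 0.25 µM,
  planting the medial–lateral couplings the indexed pairs FC21 and FC18
  measure.
* **Noise**: cardiac 1.1 Hz × 0.2 µM, respiratory 0.25 Hz × 0.1 µM, Mayer
  waves 0.1 Hz × 0.1 µM, linear drift 0.002 µM/s, white noise 0.05 µM, and
  motion artifacts (fast-decay spikes and baseline steps of ~0.2 OD) at 0.5
  events/min. Channel-level noise magnitudes for this hardware are not
  published; these values were chosen once for testability — large enough
  that the filter and motion stages do real work, small enough that planted
  structure is recoverable — and are not fidelity claims.
* **Behaviour**: instrument ranges follow the published battery (PCS-13
  0–52, PASS-20 0–100, PSEQ 0–60, CAMS-R 12–48, …); planted mean changes
  are the published group mean differences, and change SDs are derived from
  the published paired *d* values as |MD|/d. Pre-visit means are plausible
  mid-scale values consistent with the trial's inclusion thresholds
  (catastrophizing ≥ 20, pain anxiety ≥ 40), since pre-visit descriptives
  are not available. The named neural change score and the named
  instrument's change are drawn from a bivariate normal with the planted
  correlation, then affine-mapped into the instrument range with clipping;
  the clipping fraction is exported because floor effects (chiefly on the
  0–10 pain scales after large planted improvements) attenuate planted
  correlations. Per-hold pain ratings (injured ≈ 44, noninjured ≈ 3 on
  0–100) are generated as manipulation checks only.

The forward model applies the same Beer–Lambert constants the pipeline
inverts and exponentiates around baseline intensity 1.0, so with all noise
amplitudes at zero the full pipeline recovers planted betas exactly (up to
the 10⁻⁶ µM numerical bound). Everything is deterministic given the seed.

What the generator does **not** emulate: photon transport and optode
coupling physics, serially correlated physiological noise beyond fixed-
frequency oscillations, systemic (scalp) contamination, HbR-specific
effects beyond the fixed −0.25 scaling of HbO, or realistic inter-channel
noise covariance. Passing recovery tests therefore demonstrates the
correctness of the computations, not that the pipeline's estimates would be
unbiased on real hardware data.

## Numerical choices and degenerate inputs

* Half-open block intervals `[onset, onset + duration)`, 0-based time.
* Strict inequalities at both motion thresholds.
* Filter-edge transients are excluded by construction where they matter:
  tone-gain measurements use the central 60% of long signals, and GLM
  recovery spans the transient with the filtered-constant column.
* Recordings whose masked fraction exceeds `qc_ceiling = 0.5` are recorded
  as invalid — an outcome, not an exception; an empty cohort after QC is an
  explicit failure with the ledger attached.
* Channels with too few valid samples yield `NA` metrics with warnings;
  zero-variance inputs yield `NA` correlations with warnings.
* All randomness flows from explicit integer seeds kept below 2³¹.

## Problem sizes used by the tests

Most unit tests run on a shortened protocol (2 cycles per side, 40-s VR
blocks, ~260 s of signal) where every contract is scale-free. Full-protocol
runs are reserved for the round-trip, coactivation-ordering and end-to-end
checks (3–20 recordings). Statistical calibration uses the generator's
metric-level sampler — the identical code path `simulate_cohort` uses for
planted betas and behavioural scores — at 1000 null replicate cohorts and
500 powered replicates, which keeps the calibration experiment at the
spec'd replicate count without re-running 20,000 time-series
preprocessings. The acceptance script repeats these computations from
scratch against the installed package.

## Known limitations

* No short-separation regression, physiological regressors, or
  motion *correction* (only masking) — matching the modelled procedure.
* Subject-level GLM *t*-values are descriptive (no prewhitening); group
  inference uses only betas, *d* and coactivation values.
* The SNIRF interchange format is not read; the tabular bundle format is
  the supported input.
* At the study's noise levels the planted 0.075 µM channel-4 change is not
  reliably detectable through the full time-series pipeline at n = 10 —
  measurement error dominates the change-score SD. The power guarantee
  applies at the planted-beta level, which is what the paired test sees
  when measurement noise is small relative to between-visit change.
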