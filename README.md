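# nirspipe

An R package for analysing prefrontal functional near-infrared spectroscopy
(fNIRS) recordings from block-design pain and virtual-reality (VR) sessions,
together with a synthetic-data generator that makes every stage testable
against planted ground truth.

It is written for researchers running small pre/post intervention studies
with 8-channel, dual-wavelength (760/850 nm) optical topography systems over
the prefrontal cortex (PFC): movement-evoked pain paradigms, VR
relaxation/distraction blocks, and a behavioural battery (pain intensity and
interference, catastrophizing, pain anxiety, self-efficacy, mindfulness,
coping) assessed at two visits.

## What it computes

**Preprocessing.** Raw light intensities are converted to optical density,
OD(c, λ, t) = −ln(I/Ī); motion transients are flagged with a 0.5-s sliding
window (amplitude criterion 0.1 OD, 5-SD variability criterion, 1-s mask)
and masked, not repaired; a third-order zero-phase Butterworth band-pass
(0.01–0.2 Hz) removes drift and cardiac/respiratory oscillations; and the
modified Beer–Lambert law

ΔOD(λ) = [ε_HbO(λ)·ΔHbO + ε_HbR(λ)·ΔHbR] · L · DPF(λ)

is inverted per sample with age-adjusted differential pathlength factors to
give ΔHbO/ΔHbR in µM. Recordings whose masked fraction exceeds a
configurable ceiling are recorded as invalid, and a feasibility ledger
counts valid/missing/invalid recordings.

**Subject level.** Per condition: GLM activation betas (HbO regressed on
HRF-convolved block regressors, canonical double-gamma HRF), prestimulus-
baseline Cohen *d* = (mean HbO in condition − mean in the 10-s prestimulus
baseline) / pooled SD, and the 8×8 matrix of pairwise Pearson coactivation
within the condition span, indexed FC1–FC28 in lexicographic pair order with
region-pair averages over the montage's four PFC regions.

**Group level.** Paired *t*-tests on post − pre changes (MD, *t*, *p*,
paired *d* = MD/SD(diff)), Benjamini–Hochberg *q*-values per family
(channels, coactivation pairs, behavioural instruments), Pearson
brain–behaviour correlations on change scores, and sensitivity analyses
(Spearman vs time-since-injury with BH correction, leave-one-out *t*
ranges, ANCOVA with baseline, time-since-injury and injury-type
covariates).

**Synthetic cohorts.** `simulate_cohort()` generates paired pre/post raw
recordings through the exact forward model the pipeline inverts — planted
betas × (boxcar ⊗ HRF), planted shared coactivation components,
physiological noise, motion artifacts — plus behavioural tables whose
planted changes and effect sizes mirror the published battery, with a
planted brain–behaviour correlation and a full ground-truth export.

See `vignettes/fnirs-pipeline.Rmd` for the model, parameter defaults and
design decisions.

## Worked example

```r
library(nirspipe)

co  <- simulate_cohort(n_subjects = 10, seed = 1)   # study-sized cohort
res <- analyze_cohort(co, pipeline_config())
print(res)
```

```
Cohort analysis (config 7bbc4dc3, seed 1)
Of 80 possible recordings, 80 (100%) valid (0 missing, 0 invalid)
Neural changes with p < .05: 7 of 176
  cohen_d noninjured 4 (MD=+0.608, t=3.032, P=0.014, q=0.057, d=0.96)
  cohen_d noninjured 7 (MD=+0.574, t=3.399, P=0.008, q=0.057, d=1.07)
  fc injured FC18 (MD=-0.176, t=-2.896, P=0.018, q=0.496, d=-0.92)
  ...
Behavioural changes:
  NRS-rest        (MD=-3.26, P=3e-06, d=-3.23)
  PCS-13          (MD=-14.87, P=0.00014, d=-2.00)
  CAMS-R          (MD=+4.20, P=0.002, d=1.36)
  ...
```

Reading the output: 80 scheduled recordings (10 subjects × 2 visits × 4
conditions) all passed quality control. Seven neural pre/post changes reach
uncorrected *p* < .05 — at n = 10 with realistic measurement noise this is
close to the multiple-testing noise floor, which is why the BH *q*-values
stay high; the behavioural battery, whose planted changes are large,
recovers mean differences close to the planted values (e.g. pain at rest
MD = −3.26 against a planted −2.50, mindfulness +4.20 against +3.29, within
n = 10 sampling error plus range-clipping attenuation).

The file-based interface does the same from disk:

```r
write_cohort(co, "cohort_dir")
run_pipeline("cohort_dir", "results_dir", pipeline_config())
```

and a thin CLI wraps simulate/preprocess/analyze/report:

```sh
Rscript inst/cli/nirspipe.R simulate --out cohort_dir --seed 1
Rscript inst/cli/nirspipe.R run-pipeline --in cohort_dir --out results_dir
Rscript inst/cli/nirspipe.R report --in results_dir
```

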