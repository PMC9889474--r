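---
title: "Time-serial delta-radiomics for progression-free survival: methods and design"
author: "DeltaRadiomics package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-serial delta-radiomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Lung adenocarcinoma patients on EGFR tyrosine-kinase inhibitors almost all
progress eventually, but at very different speeds. A single pre-therapy CT
carries limited prognostic information; the *change* of the lesion between
the baseline scan (F0) and the first follow-up (F1) — normalized per day of
the inter-scan interval, since follow-up timing varies from 16 to 128 days —
is a more patient-specific signal, and the tissue immediately around the
tumor (the peritumoral rings) carries part of it. This package implements
the full analysis chain for that idea: ring geometry, feature extraction at
two timepoints, per-day delta features, reproducibility filtering, survival
forests with all-relevant feature selection, clinical Cox baselines,
concordance comparison, risk stratification and time-dependent ROC — plus a
synthetic cohort generator so that every stage is testable without patient
data.

## Image geometry

All feature extraction runs on a 1 mm isotropic grid (`resampleIsotropic`,
trilinear for intensities, nearest-neighbour for masks); this is the
standard harmonization step for multi-scanner data. Coordinates follow one
convention everywhere: voxel centres, 0-based indices,
`world = origin + index * spacing`, axis order (x, y, z).

Mask dilation (`dilateMm`) works in physical units via an exact Euclidean
distance transform, so "5 mm" means 5 mm at any voxel size. Distances are
taken to foreground voxel centres with a sub-voxel boundary correction of
0.2 voxels: the digitized surface of a convex object lies on average about
0.2 voxels outside its outermost voxel centres, and with this correction
the dilated voxel count of a 10 mm digital sphere matches the continuous
ball volume to ~1–2% (without it the count is ~4–6% low). The peritumoral
rings are `peri5 = dilate(tumor, 5) \ tumor` and
`peri10 = dilate(tumor, 10) \ dilate(tumor, 5)`, both intersected with the
lung mask so rings cannot breach into the chest wall or mediastinum.
Dilation is Euclidean-then-clip, not geodesic within the lung; the two
differ only for lesions whose dilation wraps around a non-convex lung
boundary, which the generator does not produce.

## Feature catalogue

Each region yields 16 first-order statistics, 6 GLCM and 6 GLRLM texture
features; shape (12 features) is computed for the tumor only, because the
rings are derived shells whose geometry is fixed by the tumor. That is 96
features per timepoint — deliberately compact. The pipeline's statistics
are catalogue-agnostic, and a compact, fully specified catalogue is
preferable to imitating a proprietary 1691-feature list whose settings are
unpublished.

Numerical choices worth knowing:

* **Discretization** is fixed-bin-number (32 equal-width bins over the
  in-region range). Synthetic intensities are not calibrated HU, so a
  fixed bin *width* has no natural scale here; range-relative binning also
  makes every texture feature invariant to intensity shifts.
* **GLCM/GLRLM** are accumulated over the 13 unique 3D unit offsets,
  symmetrized and normalized per offset, and *feature values* are averaged
  across offsets (not matrices merged); both matrix builders count only
  voxel pairs/runs entirely inside the mask, and both are tested against
  brute-force enumeration oracles.
* **Mesh features** (surface area, mesh volume, hence sphericity and
  compactness) come from a marching-tetrahedra isosurface at level 0.5 of
  the binary mask after Gaussian smoothing with sigma = 1 voxel. On a raw
  binary mask the staircase facets inflate the surface area of smooth
  objects by 25–30% (a 10 mm sphere would measure sphericity ~0.78); with
  the default smoothing the same sphere measures ~0.99 with a ~4% bias in
  mesh volume. Degenerate (planar or < 8 voxel) masks get missing mesh
  features rather than garbage.
* **Axis features** (major/minor/least axis, elongation, flatness) use a
  PCA of voxel-centre coordinates with the 4*sqrt(eigenvalue) convention.

## Reproducibility filter and per-day deltas

Test–retest reliability uses the two-way mixed-effects, absolute-agreement,
single-rater ICC — the stricter of the common choices (a systematic offset
between the two segmentations lowers it), which is what one wants when the
two measurements are supposed to be interchangeable. Features with
ICC > 0.80 on the retest subsample (30 patients by default) are retained;
the decision is made once per feature name and applied to the F0, F1 and
delta versions alike. The threshold is the conventional "excellent
reliability" cutoff and is exposed in the configuration.

The per-day delta of a retained feature is
`(f1 - f0) / (f0 * diff_days)`. Near-zero baselines would explode this
ratio, so when `|f0| <= 1e-8` times the cohort median absolute baseline the
delta is recorded as missing instead. Delta columns with more than 20%
missing values are dropped; remaining missing values are imputed with the
training-cohort median. The imputation medians, the epsilon guards and the
dropped-column list are persisted with the training table and reused
verbatim on the validation cohort — no statistic of the validation data
ever enters its own preprocessing.

## Signature construction

The survival model is a random survival forest (log-rank splitting,
sqrt(p) candidate features per split, 500 trees, `ranger` backend) whose
per-patient risk is the ensemble mortality — the ensemble cumulative hazard
summed over the unique event times. The minimal node size is 6, chosen as
the practical equivalent of "at least ~3 events per terminal node" at the
cohort's ~83% event rate (the backend counts samples, not events).

Feature selection is the shadow-feature ("Boruta") scheme wrapped around
this forest: every iteration appends an independently permuted copy of
each still-active candidate, refits the forest with OOB permutation
importance, and scores a hit for candidates beating the *maximum* shadow
importance. Two-sided binomial tests (p = 0.5) with Bonferroni correction
over the initial candidate count confirm or reject features; rejected
features leave the model matrix. Importance is the drop in OOB C-index
under column permutation — the survival-forest analogue of the Gini
importance used by the original classification formulation. Undecided
features after `maxIter` iterations stay "tentative" and are ranked below
confirmed ones, ordered by whether their median importance beats the
median shadow ceiling; ties anywhere are broken lexicographically by name
so that selection is fully deterministic under a fixed seed.

Three signatures are built per run, differing only in the candidate pool:
`all` (every column), `baseline` (F0 columns only) and `intratumor`
(tumor-region columns at any timepoint, deltas included). Each takes the
top 10 features (confirmed first), refits the forest, and maps ensemble
mortality through a training min–max scaling to a 0–100 signature score;
the scaling is persisted and applied unchanged to validation patients
(clamped with a warning outside the training range). One pooled Boruta run
per signature is used rather than separate per-timepoint runs; the pooled
run lets baseline, follow-up and delta versions of a feature compete
directly.

## Clinical baselines and model comparison

Each clinical covariate (sex, age group at 60, smoking, ethnicity, T/N/M
stage, TKI drug, baseline tumor volume) gets a univariate Cox fit (Efron
ties, Wald CIs); the multivariable clinical model is built by classic
greedy forward selection on AIC — add the covariate with the largest AIC
decrease, stop when nothing improves, prefer fewer parameters on ties
below 1e-6. Degenerate fits (constant covariate, separation,
non-convergence) are flagged, not fatal. The combined clinico-radiomics
model is a Cox fit on the signature score plus the selected clinical
covariates, with the linear predictor as risk.

Models are compared by Harrell's C. Comparable pairs require the shorter
observed time to be an event; risk ties earn 0.5. The paired comparison of
two models' C-indices is a patient-level bootstrap of the difference
(same resample applied to both scores), with the two-sided
`2 * min(P(dC* <= 0), P(dC* >= 0))` p-value and the (+1)/(n+1)
small-sample correction. The reference publication style names only "a
pairwise nonparametric test"; the paired bootstrap was chosen over a
jackknife variance test because it is distribution-free and respects the
pairing of predictions on the same patients. Identical scores return
p = 1 by convention.

## Risk stratification and time-dependent accuracy

The signature-score cutoff is found by maximally selected log-rank
statistics: the two-sample log-rank chi-square is evaluated at every
observed score inside the 10%–90% quantile range (a guard against
degenerate small groups), and the maximizing cutoff splits patients into
"rapid" (score above) and "slow" progressors. The search is exhaustive
over candidates, so the returned statistic is the profile maximum by
construction. Because the cutoff maximizes the statistic, the plain
log-rank p on the induced split is anti-conservative; the report flags
this and also carries a permutation-adjusted p (the cutoff search re-run
on 200 permutations of the scores). The training cutoff is applied
unchanged to the validation cohort.

Kaplan–Meier medians use the right-continuous step convention (first time
the curve reaches 0.5 or below; undefined if it never does). The
time-dependent ROC is cumulative-cases / dynamic-controls with inverse
probability of censoring weights from the Kaplan–Meier estimator of the
censoring distribution, evaluated at 6, 9 and 12 months; with no censoring
before a horizon it reduces exactly to the Mann–Whitney AUC of cases
versus controls, which is one of its tests.

## The synthetic cohort

The generator emulates the *structure* of a two-timepoint EGFR-TKI imaging
study: 131 training and 41 validation patients; inter-scan intervals
log-normal with median 35 days truncated to [16, 128]; ~83% progression
events; clinical covariates drawn from realistic marginal frequencies and
— by default — independent of outcome, reproducing the "weak clinical
baseline" regime (a configuration switch can add a weak volume effect of
the order HR ~ 1.006/mL).

Each lesion is an ellipsoid (baseline volumes log-normal, median 15 mL,
clipped to at least ~10 mm diameter) with three appearance components: a
core intensity, a Gaussian-random-field texture (smoothed white noise,
correlation length 3 mm) scaled by a per-patient amplitude (log-normal,
sdlog 0.45 — spread enough that the baseline texture features read the
amplitude reliably), and a
peritumoral rim that decays exponentially from the core value to lung
background at a per-patient rate per mm. A chest-wall slab of high
intensity is placed next to ~30% of lesions to exercise ring clipping.
Between F0 and F1 three per-day rates evolve the lesion: volume
(`V1 = V0 * (1 + rate * days)`), texture amplitude, and rim decay. The
same texture field underlies both timepoints, so feature deltas reflect
the planted rates rather than fresh noise. The latent risk is the
weighted sum of the three rates plus a small baseline-texture term
(weights 260 / 170 / 240 / 0.85), and event times are exponential with
hazard proportional to `exp(latent risk)` around a 10-month baseline
scale, censored by a uniform time over 0–300 months. The weights and
censor window were fixed once so that the event fraction is ~0.83, the
median PFS ~11–12 months, and the C-index of the *true* latent risk ~0.82
— an upper bound any fitted model stays below. The baseline-texture term
gives F0-only models a weak but real signal, the tumor-volume and texture
rates are recoverable from intratumoral columns, and the rim rate only
from peritumoral columns: by construction the comprehensive signature
should beat the intratumoral one, which should beat the baseline one,
with the clinical model near chance.

The retest segmentation perturbs the F0 mask boundary with a smooth random
displacement field bounded by 1.5 mm (Dice >= 0.95 typically). On a 1 mm
grid this leaves coarse first-order and shape features stable while
destabilizing fine texture in the thin rings, so the ICC filter retains
roughly half the catalogue — qualitatively the regime real test–retest
studies report.

What the generator does *not* emulate: CT physics (beam hardening, dose,
reconstruction kernels), respiratory motion, scanner-to-scanner batch
effects, non-ellipsoidal growth patterns, or real peritumoral biology.
Passing tests on this cohort demonstrate that the pipeline recovers a
known planted signal with correct statistical behaviour — not that the
specific features selected here are the ones real lesions would yield.

## Problem sizes and determinism

Default runs use the full 131 + 41 cohort with 500-tree final forests,
300-tree selection forests and at most 50 Boruta iterations; the test
suite exercises reduced configurations (smaller lesions, fewer trees and
iterations) chosen to probe the same properties at a fraction of the
cost. Every stage derives its seed from the master seed and the stage name
(`stageSeed`), so any stage can be re-run in isolation and two runs with
the same configuration and seed produce identical reports.

## Known limitations

* The feature catalogue omits filtered-image (wavelet/LoG) features and
  the GLSZM/NGTDM families, and is not IBSI-certified.
* The ICC filter models intra-observer test–retest only; multi-rater
  reliability and scanner harmonization (e.g. ComBat) are out of scope.
* Exponential event times imply proportional hazards by construction;
  the Cox and forest models are therefore never tested under
  non-proportionality here.
* `simulateSurvival`'s uniform censoring is a simple stand-in for the mix
  of administrative censoring and loss to follow-up in real studies.
* With a 41-patient validation cohort the C-index differences between
  adjacent feature pools (~0.05–0.10) are of the same order as their
  sampling error (~0.06), so on any single simulated cohort an adjacent
  pair of models can invert even though the planted ordering holds in
  expectation — the same caveat applies to small external cohorts in real
  studies.
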