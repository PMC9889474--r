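# DeltaRadiomics

Time-serial CT delta-radiomics signatures for progression-free survival
(PFS) under targeted therapy.

## The problem

Lung adenocarcinoma patients on EGFR tyrosine-kinase inhibitors (EGFR-TKIs)
respond, then almost invariably progress as resistance emerges — at very
different speeds. A single pre-therapy CT carries limited prognostic
information. This package implements a longitudinal alternative: extract
intensity/shape/texture (radiomics) features from the tumor *and* its
peritumoral rings on the baseline scan (F0) and the first follow-up (F1),
convert each feature to a per-day rate of change

```
delta = (1 / Diff_time) * (f_F1 - f_F0) / f_F0
```

(normalizing for follow-up intervals that range from 16 to 128 days), and
build a survival-forest signature from the features that survive a
test–retest reliability filter. For a patient row `x` with observed PFS
outcome `(T, δ)`, the chain is:

* **Ring geometry** — `peri5 = dilate(tumor, 5 mm) \ tumor`,
  `peri10 = dilate(tumor, 10 mm) \ dilate(tumor, 5 mm)`, dilation by exact
  Euclidean distance transform in physical units, rings clipped to the
  lung mask; everything on a 1×1×1 mm resampled grid.
* **Features** — 16 first-order + 6 GLCM + 6 GLRLM per region, 12 shape
  features for the tumor (96 per timepoint), with brute-force-verified
  texture matrices over the 13 unique 3D directions.
* **Reliability** — two-way mixed-effects absolute-agreement ICC on a
  repeated segmentation of F0; keep features with ICC > 0.80.
* **Selection/model** — Boruta shadow-feature selection wrapped around a
  random survival forest (log-rank splits, √p mtry, OOB permutation
  importance); the top 10 features refit as the signature, scored 0–100
  by min–max-scaled ensemble mortality. Three pools are fitted: all
  features, baseline-only, intratumoral-only.
* **Evaluation** — clinical Cox baselines (univariate + forward-AIC),
  Harrell's C with a paired patient-level bootstrap for model comparison,
  maximally selected log-rank cutoff for rapid/slow stratification,
  Kaplan–Meier curves, and cumulative/dynamic time-dependent ROC with
  IPCW at 6/9/12 months.

No public imaging cohort accompanies the design, so the package ships a
synthetic lesion-pair generator (`simulateCohort`) that plants a known
prognostic signal in the per-day deltas and peritumoral rim of ellipsoidal
lesions on a lung-like background; every stage of the pipeline is tested
against it and against analytic oracles.

## Worked example

Simulate one patient's scan pair (a lesion growing 1%/day over a 50-day
interval), build the rings, and extract features:

```r
library(DeltaRadiomics)
p    <- lesionParams(centerMm = c(30, 28, 28), radiiMm = c(12, 11, 10))
prof <- progressionProfile(volumeRatePerDay = 0.01,
                           textureRatePerDay = 0, periRatePerDay = -0.005)
pair <- simulateLesionPair(p, prof, intervalDays = 50,
                           gridSpec = list(dim = c(59, 55, 55)), seed = 7)
pair
#> ScanPair: interval 50 days; F0 tumor 5463 vox, F1 tumor 8281 vox

v0 <- maskVolumeMl(scanMask(pair, "F0"))
v1 <- maskVolumeMl(scanMask(pair, "F1"))
cat(sprintf("F0 %.2f mL, F1 %.2f mL, per-day delta %.4f\n",
            v0, v1, deltaPerDay(v0, v1, 50)))
#> F0 5.46 mL, F1 8.28 mL, per-day delta 0.0103

rings <- makeRings(scanMask(pair, "F0"), lungMask(pair))
#> rings[?]: tumor=5463 peri5=11646 peri10=21498 voxels
fv <- extractFeatures(scanGrid(pair, "F0"), rings, "F0")
round(fv[c("F0__tumor__shape__sphericity", "F0__tumor__glcm__contrast",
           "F0__peri5__first_order__mean")], 3)
#> F0__tumor__shape__sphericity    F0__tumor__glcm__contrast
#>                        0.990                       13.565
#> F0__peri5__first_order__mean
#>                     -424.359
```

The recovered per-day volume delta (0.0103) matches the planted rate
(0.01); the near-spherical lesion scores sphericity 0.99; the peri5 mean
sits between the tumor core and the −800 HU lung background, as the rim
model dictates.

The full study replica — simulate a 131 + 41 patient cohort, extract
everything, filter, select, fit the three signatures and the clinical
model, compare C-indices and stratify — is one call:

```r
res <- runPipeline(seed = 1, outDir = "run1")
res$cindex$model_all$valid$c        # held-out C-index of the signature
#> [1] 0.7462121
res$stratification$report$cutoff    # training maxstat cutoff score
#> [1] 63.05012
```

At seed 1 the held-out C-indices order as the construction plants them:
comprehensive signature 0.746, intratumoral-only 0.677, baseline-only
0.530, clinical Cox model 0.508; the combined clinico-radiomics model
(0.745) adds nothing over the signature, and the rapid-progression group's
median PFS is shorter than the slow group's in both cohorts.

It writes `run1/report.json` plus Kaplan–Meier, maxstat-profile and tdROC
figures under `run1/report/`. A thin command-line wrapper is installed at
`inst/scripts/deltarad.R` (`simulate` and `run-all` subcommands).

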