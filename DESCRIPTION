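Package: DeltaRadiomics
Title: Time-Serial CT Delta-Radiomics Signatures for Progression-Free
    Survival
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for longitudinal (two-timepoint) CT radiomics analysis of
    lung lesions under targeted therapy: peritumoral ring construction by
    physical-unit mask dilation with organ clipping, a compact catalogue of
    first-order, shape and texture (GLCM/GLRLM) features, test-retest ICC
    reproducibility filtering, per-day delta features, Boruta feature
    selection wrapped around random survival forests, clinical Cox baselines,
    concordance-index model comparison, maximally selected log-rank risk
    stratification, and time-dependent ROC with censoring weights. Includes
    a synthetic time-serial lesion cohort generator with a planted
    progression signal so the full pipeline can be exercised end to end
    without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    RNifti,
    survival,
    ranger,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
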