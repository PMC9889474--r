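# Configuration validation and one-command orchestration of the full
# analysis on a synthetic cohort.

.pipeline_defaults <- function() {
  c(defaultCohortConfig(),
    list(iccThreshold = 0.80, nBins = 32, kSignature = 10,
         rsfTrees = 500, borutaTrees = 300, borutaMaxIter = 50,
         borutaAlpha = 0.05, maxstatLower = 0.10, maxstatUpper = 0.90,
         horizons = c(6, 9, 12), nBootAUC = 200, nBootCompare = 1000,
         nPermutations = 200, clinicalVolumeEffect = 0))
}

#' Validate a pipeline configuration
#'
#' Fills defaults, rejects unknown keys, and checks value ranges. Accepts
#' a named list or a path to a JSON file; an empty file or list yields all
#' defaults. The result round-trips through JSON serialization.
#'
#' @param config named list of overrides, or a JSON file path.
#' @return the completed configuration list.
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config)) {
    txt <- paste(readLines(config, warn = FALSE), collapse = "\n")
    config <- if (nzchar(trimws(txt)))
      jsonlite::fromJSON(txt, simplifyVector = TRUE) else list()
  }
  stopifnot(is.list(config))
  defaults <- .pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): /",
         paste(unknown, collapse = ", /"))
  cfg <- modifyList(defaults, config)
  if (cfg$iccThreshold > 1)
    stop("/iccThreshold: must be <= 1")
  if (cfg$iccThreshold < -1) stop("/iccThreshold: must be >= -1")
  if (cfg$nTrain + cfg$nValid < 10)
    stop("/nTrain + /nValid: cohort must have at least 10 patients")
  if (cfg$intervalMin < 1 || cfg$intervalMax <= cfg$intervalMin)
    stop("/intervalMin, /intervalMax: need 1 <= min < max")
  if (cfg$kSignature < 1) stop("/kSignature: must be >= 1")
  if (cfg$maxstatLower < 0 || cfg$maxstatUpper > 1 ||
      cfg$maxstatLower >= cfg$maxstatUpper)
    stop("/maxstatLower, /maxstatUpper: need 0 <= lower < upper <= 1")
  if (any(cfg$horizons <= 0)) stop("/horizons: must be positive months")
  if (cfg$baselineScale <= 0) stop("/baselineScale: must be > 0")
  cfg
}

# strip the timepoint prefix from structured feature names
.strip_tp <- function(x) sub("^(F0|F1)__", "", x)

#' Extract features for every patient of a cohort directory
#'
#' Reads each patient's volumes, resamples to 1 mm isotropic, builds the
#' ring regions (F0, F1, and the retest segmentation of F0) and extracts
#' the full catalogue. Returns the three per-timepoint feature tables.
#'
#' @param dir cohort directory written by [simulateCohort()].
#' @param nBins discretization levels.
#' @param quiet suppress per-patient ring messages.
#' @return list of data.frames `F0`, `F1`, `retest` (the retest table has
#'   timepoint-stripped names).
#' @export
extractCohortFeatures <- function(dir, nBins = 32, quiet = TRUE) {
  ids <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  rows0 <- list(); rows1 <- list(); rowsR <- list()
  for (id in ids) {
    p <- file.path(dir, id)
    f0 <- resampleIsotropic(readVolume(file.path(p, "F0.nii.gz")))
    f1 <- resampleIsotropic(readVolume(file.path(p, "F1.nii.gz")))
    m0 <- resampleIsotropic(readVolume(file.path(p, "F0_mask.nii.gz"),
                                       mask = TRUE))
    m1 <- resampleIsotropic(readVolume(file.path(p, "F1_mask.nii.gz"),
                                       mask = TRUE))
    mr <- resampleIsotropic(readVolume(
      file.path(p, "F0_mask_retest.nii.gz"), mask = TRUE))
    lung <- resampleIsotropic(readVolume(file.path(p, "lung_mask.nii.gz"),
                                         mask = TRUE))
    ring <- function(tm) {
      if (quiet) suppressMessages(makeRings(tm, lung, patientId = id))
      else makeRings(tm, lung, patientId = id)
    }
    rows0[[id]] <- extractFeatures(f0, ring(m0), "F0", nBins = nBins)
    rows1[[id]] <- extractFeatures(f1, ring(m1), "F1", nBins = nBins)
    fr <- extractFeatures(f0, ring(mr), "F0", nBins = nBins)
    names(fr) <- .strip_tp(names(fr))
    rowsR[[id]] <- fr
  }
  asTab <- function(rows) {
    tab <- as.data.frame(do.call(rbind, rows))
    cbind(data.frame(patient_id = names(rows), stringsAsFactors = FALSE),
          tab)
  }
  list(F0 = asTab(rows0), F1 = asTab(rows1), retest = asTab(rowsR))
}

#' Run the full analysis on a synthetic cohort
#'
#' One-command replica of the study workflow: simulate the cohort, extract
#' features at both timepoints (plus the retest segmentation), filter by
#' test-retest ICC, assemble per-day delta features, build the three
#' radiomics signatures (all / baseline / intratumor), fit the clinical
#' Cox baselines and the combined model, compare concordance indices, and
#' stratify both cohorts with time-dependent ROC. All stage seeds derive
#' from the master seed.
#'
#' @param config configuration list or JSON path (see [validateConfig()]).
#' @param seed master seed.
#' @param outDir output directory for the cohort, tables and report
#'   (`NULL` for a temporary directory).
#' @param quiet suppress progress messages.
#' @return a list with the fitted models, score tables, comparisons,
#'   stratification and the report (also written to
#'   `<outDir>/report.json`).
#' @export
runPipeline <- function(config = list(), seed = 1, outDir = NULL,
                        quiet = FALSE) {
  cfg <- validateConfig(config)
  if (is.null(outDir)) outDir <- tempfile("deltarad_run_")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)

  say("stage 1/8: simulating cohort (", cfg$nTrain, " train + ",
      cfg$nValid, " valid)")
  cohortDir <- file.path(outDir, "cohort")
  sim <- simulateCohort(cfg[names(defaultCohortConfig())],
                        seed = stageSeed(seed, "simulate"),
                        dir = cohortDir,
                        clinicalVolumeEffect = cfg$clinicalVolumeEffect)

  say("stage 2/8: extracting features (3 regions x 2 timepoints + retest)")
  feats <- extractCohortFeatures(cohortDir, nBins = cfg$nBins)

  isTrain <- sim$cohort == "train"
  trainIds <- sim$clinical$patient_id[isTrain]
  validIds <- sim$clinical$patient_id[!isTrain]

  say("stage 3/8: test-retest ICC filter (threshold ", cfg$iccThreshold,
      ")")
  retestIds <- with_seed(stageSeed(seed, "retest_sample"),
                         sample(trainIds, min(cfg$nRetest,
                                              length(trainIds))))
  scanTab <- feats$F0[feats$F0$patient_id %in% retestIds, , drop = FALSE]
  colnames(scanTab) <- c("patient_id",
                         .strip_tp(colnames(scanTab)[-1]))
  retTab <- feats$retest[feats$retest$patient_id %in% retestIds, ,
                         drop = FALSE]
  icc <- retestFilter(scanTab, retTab, threshold = cfg$iccThreshold)
  say("  retained ", length(icc$retained), " / ",
      nrow(icc$report), " features")

  say("stage 4/8: delta features and table assembly")
  asmTrain <- assembleFeatureTable(
    feats$F0[feats$F0$patient_id %in% trainIds, ],
    feats$F1[feats$F1$patient_id %in% trainIds, ],
    icc$retained, sim$intervals)
  asmValid <- assembleFeatureTable(
    feats$F0[feats$F0$patient_id %in% validIds, ],
    feats$F1[feats$F1$patient_id %in% validIds, ],
    icc$retained, sim$intervals, reference = asmTrain)

  oc <- sim$outcomes
  yTrain <- oc[match(asmTrain@table$patient_id, oc$patient_id), ]
  yValid <- oc[match(asmValid@table$patient_id, oc$patient_id), ]

  say("stage 5/8: signature construction (Boruta + survival forest)")
  pools <- c("all", "baseline", "intratumor")
  signatures <- lapply(pools, function(p) {
    say("  pool: ", p)
    buildSignature(asmTrain, yTrain$pfs_months, yTrain$event, pool = p,
                   k = cfg$kSignature, nTrees = cfg$rsfTrees,
                   borutaTrees = cfg$borutaTrees,
                   maxIter = cfg$borutaMaxIter, alpha = cfg$borutaAlpha,
                   seed = stageSeed(seed, "signature"))
  })
  names(signatures) <- pools
  scores <- lapply(signatures, function(m) {
    list(train = signatureScore(m, asmTrain@table),
         valid = signatureScore(m, asmValid@table))
  })

  say("stage 6/8: clinical Cox baselines")
  clin <- .prepare_clinical(sim$clinical)
  clinTrain <- clin[match(asmTrain@table$patient_id, clin$patient_id), ]
  clinValid <- clin[match(asmValid@table$patient_id, clin$patient_id), ]
  candidates <- setdiff(colnames(clin), "patient_id")
  uni <- lapply(candidates, function(cn) {
    coxUnivariate(clinTrain[[cn]], yTrain$pfs_months, yTrain$event,
                  name = cn)
  })
  names(uni) <- candidates
  fwd <- coxForwardAIC(clinTrain[candidates], yTrain$pfs_months,
                       yTrain$event)
  say("  clinical model covariates: ",
      if (length(fwd$selected)) paste(fwd$selected, collapse = ", ")
      else "(null model)")
  clinRisk <- .clinical_risk(fwd, clinTrain, clinValid)

  comb <- combineClinicoRadiomics(scores$all$train,
                                  clinTrain[fwd$selected],
                                  yTrain$pfs_months, yTrain$event)
  combRisk <- .combined_risk(comb, scores$all, clinTrain, clinValid,
                             fwd$selected)

  say("stage 7/8: concordance comparison")
  riskSets <- list(
    model_all = list(train = scores$all$train,
                     valid = scores$all$valid),
    model_baseline = list(train = scores$baseline$train,
                          valid = scores$baseline$valid),
    model_intratumor = list(train = scores$intratumor$train,
                            valid = scores$intratumor$valid),
    model_clinical = clinRisk,
    model_combined = combRisk)
  cseed <- stageSeed(seed, "cindex")
  cindex <- lapply(riskSets, function(rs) {
    list(train = harrellC(rs$train, yTrain$pfs_months, yTrain$event,
                          nBoot = 1000, seed = cseed),
         valid = harrellC(rs$valid, yValid$pfs_months, yValid$event,
                          nBoot = 1000, seed = cseed))
  })
  pairsToTest <- list(c("model_all", "model_clinical"),
                      c("model_all", "model_baseline"),
                      c("model_all", "model_intratumor"),
                      c("model_combined", "model_all"))
  comparisons <- lapply(pairsToTest, function(pr) {
    lapply(c(train = "train", valid = "valid"), function(coh) {
      y <- if (coh == "train") yTrain else yValid
      compareCPaired(riskSets[[pr[1]]][[coh]], riskSets[[pr[2]]][[coh]],
                     y$pfs_months, y$event, nBoot = cfg$nBootCompare,
                     seed = cseed)$p
    })
  })
  names(comparisons) <- vapply(pairsToTest, paste, collapse = "_vs_",
                               FUN.VALUE = character(1))

  say("stage 8/8: risk stratification and time-dependent ROC")
  strat <- stratifyAndReport(
    scores$all$train, yTrain$pfs_months, yTrain$event,
    scores$all$valid, yValid$pfs_months, yValid$event,
    horizons = cfg$horizons,
    quantileRange = c(cfg$maxstatLower, cfg$maxstatUpper),
    nPermutations = cfg$nPermutations, nBoot = cfg$nBootAUC,
    outDir = file.path(outDir, "report"),
    seed = stageSeed(seed, "stratify"))

  report <- list(
    seed = seed,
    config = cfg,
    n_train = nrow(asmTrain@table), n_valid = nrow(asmValid@table),
    event_fraction = mean(oc$event),
    icc_retained = length(icc$retained),
    icc_total = nrow(icc$report),
    signature_features = lapply(signatures, function(m) m@features),
    c_index = lapply(cindex, function(x)
      list(train = x$train$c, train_ci = x$train$ci,
           valid = x$valid$c, valid_ci = x$valid$ci)),
    comparisons_p = comparisons,
    stratification = strat$report)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")

  invisible(list(config = cfg, dir = outDir, simulation = sim,
                 features = feats, icc = icc,
                 assembled = list(train = asmTrain, valid = asmValid),
                 outcomes = list(train = yTrain, valid = yValid),
                 signatures = signatures, scores = scores,
                 clinical = list(univariate = uni, forward = fwd,
                                 risk = clinRisk),
                 combined = comb, cindex = cindex,
                 comparisons = comparisons, stratification = strat,
                 report = report))
}

# clinical covariates as modeling variables (age dichotomized at 60)
.prepare_clinical <- function(clinical) {
  data.frame(
    patient_id = clinical$patient_id,
    sex = factor(clinical$sex, levels = c("female", "male")),
    age_group = factor(ifelse(clinical$age >= 60, ">=60", "<60"),
                       levels = c("<60", ">=60")),
    smoking = factor(clinical$smoking, levels = c("no", "yes")),
    ethnicity = factor(clinical$ethnicity,
                       levels = c("han", "minority")),
    t_stage = factor(clinical$t_stage,
                     levels = c("T1", "T2", "T3", "T4")),
    n_stage = factor(clinical$n_stage,
                     levels = c("N0", "N1", "N2", "N3")),
    m_stage = factor(clinical$m_stage, levels = c("M0", "M1")),
    tki_drug = factor(clinical$tki_drug,
                      levels = c("afatinib", "erlotinib", "gefitinib",
                                 "icotinib", "osimertinib")),
    baseline_volume_ml = clinical$baseline_volume_ml,
    stringsAsFactors = FALSE)
}

.clinical_risk <- function(fwd, clinTrain, clinValid) {
  if (length(fwd$selected) == 0 || is.null(fwd$fit) ||
      length(coef(fwd$fit)) == 0) {
    # null clinical model: constant risk
    return(list(train = rep(0, nrow(clinTrain)),
                valid = rep(0, nrow(clinValid))))
  }
  list(train = unname(predict(fwd$fit, newdata = clinTrain,
                              type = "lp")),
       valid = unname(predict(fwd$fit, newdata = clinValid,
                              type = "lp")))
}

.combined_risk <- function(comb, scoresAll, clinTrain, clinValid,
                           selected) {
  ndT <- cbind(data.frame(signature = scoresAll$train),
               clinTrain[selected])
  ndV <- cbind(data.frame(signature = scoresAll$valid),
               clinValid[selected])
  list(train = unname(predict(comb$fit, newdata = ndT, type = "lp")),
       valid = unname(predict(comb$fit, newdata = ndV, type = "lp")))
}
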