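# Train/validation risk stratification with plots and a JSON summary.

#' Stratify training and validation cohorts and report
#'
#' The cutoff is determined on the training cohort only (maximally selected
#' log-rank statistic) and applied unchanged to the validation cohort.
#' Emits Kaplan-Meier plots, the maxstat profile, time-dependent ROC AUCs,
#' and a JSON summary. Because the cutoff maximizes the statistic, the
#' plain training log-rank p is anti-conservative; a permutation-adjusted
#' p (re-running the cutoff search on permuted scores) is reported next to
#' it.
#'
#' @param scoresTrain,scoresValid signature scores per cohort.
#' @param timeTrain,eventTrain,timeValid,eventValid outcomes per cohort.
#' @param horizons tdROC horizons in months.
#' @param quantileRange maxstat search range.
#' @param nPermutations permutations for the adjusted training p.
#' @param nBoot bootstrap resamples for AUC CIs.
#' @param outDir output directory for `report.json` and PNG figures
#'   (`NULL` to skip file output).
#' @param seed integer seed.
#' @return a list with `train` and `valid`
#'   [StratificationResult-class]-like entries, `tdauc` per cohort, and
#'   `report` (the summary list written as JSON).
#' @export
stratifyAndReport <- function(scoresTrain, timeTrain, eventTrain,
                              scoresValid, timeValid, eventValid,
                              horizons = c(6, 9, 12),
                              quantileRange = c(0.10, 0.90),
                              nPermutations = 200, nBoot = 200,
                              outDir = NULL, seed = 1) {
  strat <- maxstatCutoff(scoresTrain, timeTrain, eventTrain,
                         quantileRange = quantileRange)

  # permutation-adjusted p for the maximally selected statistic
  permP <- NA_real_
  if (nPermutations > 0) {
    obs <- max(strat@profile$statistic)
    permMax <- with_seed(stageSeed(seed, "maxstat_perm"), {
      vapply(seq_len(nPermutations), function(b) {
        sc <- sample(scoresTrain)
        qr <- quantile(sc, quantileRange)
        cand <- sort(unique(sc[sc >= qr[1] & sc <= qr[2]]))
        cand <- cand[cand < max(sc)]
        max(.logrank_profile_cpp(as.numeric(timeTrain),
                                 as.integer(eventTrain),
                                 as.numeric(sc), as.numeric(cand)))
      }, numeric(1))
    })
    permP <- (1 + sum(permMax >= obs)) / (nPermutations + 1)
  }
  strat@logrank <- c(strat@logrank, p_permutation = permP)

  groupsValid <- factor(ifelse(scoresValid > strat@cutoff, "rapid",
                               "slow"), levels = c("rapid", "slow"))
  validOk <- all(table(groupsValid) > 0)
  if (!validOk)
    warning("validation cohort has an empty risk group; ",
            "group-level statistics suppressed")
  medValid <- if (validOk)
    .km_median_by_group(timeValid, eventValid, groupsValid)
  else c(rapid = NA_real_, slow = NA_real_)
  lrValid <- if (validOk && all(tapply(eventValid, groupsValid, sum) >= 1))
    logrankTest(timeValid, eventValid, groupsValid)
  else list(statistic = NA_real_, p = NA_real_)

  feasible <- function(time, event, hs) {
    ok <- vapply(hs, function(h) {
      h < max(time) && sum(time <= h & event == 1) >= 5 &&
        sum(time > h) >= 5
    }, logical(1))
    if (!all(ok))
      warning("dropping horizon(s) without >= 5 cases and controls: ",
              paste(hs[!ok], collapse = ", "))
    hs[ok]
  }
  hTrain <- feasible(timeTrain, eventTrain, horizons)
  hValid <- feasible(timeValid, eventValid, horizons)
  aucTrain <- if (length(hTrain))
    timeDependentAUC(scoresTrain, timeTrain, eventTrain,
                     horizons = hTrain, nBoot = nBoot,
                     seed = stageSeed(seed, "tdauc_train"))
  else data.frame(horizon = numeric(0), auc = numeric(0),
                  ci_lower = numeric(0), ci_upper = numeric(0),
                  n_cases = integer(0), n_controls = integer(0))
  aucValid <- if (length(hValid))
    timeDependentAUC(scoresValid, timeValid, eventValid,
                     horizons = hValid, nBoot = nBoot,
                     seed = stageSeed(seed, "tdauc_valid"))
  else data.frame(horizon = numeric(0), auc = numeric(0),
                  ci_lower = numeric(0), ci_upper = numeric(0),
                  n_cases = integer(0), n_controls = integer(0))

  report <- list(
    cutoff = strat@cutoff,
    note = paste("training log-rank p after maximal selection is",
                 "anti-conservative; see p_permutation"),
    train = list(
      n = length(scoresTrain),
      n_rapid = sum(strat@groups == "rapid"),
      n_slow = sum(strat@groups == "slow"),
      median_pfs_rapid = strat@medianPFS[["rapid"]],
      median_pfs_slow = strat@medianPFS[["slow"]],
      logrank_statistic = strat@logrank[["statistic"]],
      logrank_p = strat@logrank[["p"]],
      logrank_p_permutation = permP,
      tdauc = aucTrain),
    valid = list(
      n = length(scoresValid),
      n_rapid = sum(groupsValid == "rapid"),
      n_slow = sum(groupsValid == "slow"),
      median_pfs_rapid = medValid[["rapid"]],
      median_pfs_slow = medValid[["slow"]],
      logrank_statistic = lrValid$statistic,
      logrank_p = lrValid$p,
      tdauc = aucValid))

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    .plot_km_png(timeTrain, eventTrain, strat@groups,
                 file.path(outDir, "km_train.png"), "Training cohort")
    if (validOk)
      .plot_km_png(timeValid, eventValid, groupsValid,
                   file.path(outDir, "km_valid.png"), "Validation cohort")
    grDevices::png(file.path(outDir, "maxstat_profile.png"), 600, 450)
    plot(strat@profile$cutoff, strat@profile$statistic, type = "l",
         xlab = "signature score cutoff", ylab = "log-rank chi-square",
         main = "Maximally selected log-rank profile")
    graphics::abline(v = strat@cutoff, lty = 2)
    grDevices::dev.off()
    .plot_tdroc_png(rbind(cbind(aucTrain, cohort = "train"),
                          cbind(aucValid, cohort = "valid")),
                    file.path(outDir, "tdroc.png"))
  }

  list(train = strat,
       valid = list(groups = groupsValid, medianPFS = medValid,
                    logrank = lrValid),
       tdauc = list(train = aucTrain, valid = aucValid),
       report = report)
}

.plot_km_png <- function(time, event, groups, path, title) {
  grDevices::png(path, 600, 450)
  km <- kmEstimate(time, event, groups)
  plot(km$fit, col = c(2, 4), lwd = 2, xlab = "months",
       ylab = "progression-free fraction", main = title)
  graphics::legend("topright", legend = levels(groups), col = c(2, 4),
                   lwd = 2)
  grDevices::dev.off()
}

.plot_tdroc_png <- function(aucTab, path) {
  grDevices::png(path, 600, 450)
  plot(NA, xlim = range(aucTab$horizon), ylim = c(0, 1),
       xlab = "horizon (months)", ylab = "AUC(t)",
       main = "Time-dependent ROC AUC")
  for (coh in unique(aucTab$cohort)) {
    sub <- aucTab[aucTab$cohort == coh, ]
    graphics::lines(sub$horizon, sub$auc, type = "b",
                    col = ifelse(coh == "train", 2, 4), lwd = 2)
  }
  graphics::abline(h = 0.5, lty = 3)
  graphics::legend("bottomright", legend = unique(aucTab$cohort),
                   col = c(2, 4), lwd = 2)
  grDevices::dev.off()
}
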