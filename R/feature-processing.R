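# Test-retest reproducibility filtering and per-day delta features.

#' Intraclass correlation coefficient (two-way mixed, absolute agreement,
#' single rater)
#'
#' ICC from the standard mean-squares decomposition with k = 2 repeated
#' measurements per subject:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`.
#' Absolute agreement penalizes systematic offsets between measurements.
#' When the total variance is zero (identical constant measurements) the
#' ICC is 1 by convention.
#'
#' @param measure1,measure2 paired per-subject values (n >= 3, finite).
#' @return the ICC estimate (may fall below 0).
#' @examples
#' x <- rnorm(30)
#' computeICC(x, x)  # 1
#' @export
computeICC <- function(measure1, measure2) {
  stopifnot(length(measure1) == length(measure2))
  ok <- is.finite(measure1) & is.finite(measure2)
  x <- measure1[ok]; y <- measure2[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired finite observations")
  k <- 2
  subjMean <- (x + y) / 2
  grand <- mean(c(x, y))
  ssr <- k * sum((subjMean - grand)^2)
  ratMean <- c(mean(x), mean(y))
  ssc <- n * sum((ratMean - grand)^2)
  sst <- sum((c(x, y) - grand)^2)
  sse <- sst - ssr - ssc
  if (sst < .Machine$double.eps * max(1, grand^2)) return(1.0)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- max(sse / ((n - 1) * (k - 1)), 0)
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' Test-retest reproducibility filter
#'
#' Per-feature ICC between the original-scan and retest feature tables; a
#' feature is retained when its ICC exceeds `threshold` (default 0.80,
#' "excellent reliability"). The decision is made once per feature name and
#' then applies to the F0, F1 and delta versions of that feature.
#'
#' @param featuresScan,featuresRetest data.frames with a `patient_id`
#'   column and identical feature columns (retest on >= 30 patients is the
#'   intended design).
#' @param threshold ICC retention threshold.
#' @return a list with `report` (data.frame: feature, icc, retained) and
#'   `retained` (character vector of feature names).
#' @export
retestFilter <- function(featuresScan, featuresRetest, threshold = 0.80) {
  f1 <- setdiff(colnames(featuresScan), "patient_id")
  f2 <- setdiff(colnames(featuresRetest), "patient_id")
  if (!setequal(f1, f2)) {
    off <- c(setdiff(f1, f2), setdiff(f2, f1))
    stop("feature name mismatch between scan and retest tables: ",
         paste(head(off, 10), collapse = ", "))
  }
  ids <- intersect(featuresScan$patient_id, featuresRetest$patient_id)
  a <- featuresScan[match(ids, featuresScan$patient_id), f1, drop = FALSE]
  b <- featuresRetest[match(ids, featuresRetest$patient_id), f1,
                      drop = FALSE]
  icc <- vapply(f1, function(fn) {
    tryCatch(computeICC(a[[fn]], b[[fn]]), error = function(e) NA_real_)
  }, numeric(1))
  report <- data.frame(feature = f1, icc = unname(icc),
                       retained = !is.na(icc) & icc > threshold)
  list(report = report, retained = report$feature[report$retained])
}

#' Per-day fractional feature change
#'
#' The per-day percentage variation
#' `delta = (f1 - f0) / (f0 * diffDays)`, guarded against near-zero
#' baselines: when `|f0| <= epsilon` the delta is missing (`NA`) rather
#' than exploding.
#'
#' @param f0,f1 feature values at baseline and first follow-up.
#' @param diffDays inter-scan interval in days (>= 1).
#' @param epsilon near-zero guard for the baseline value.
#' @return per-day fractional change, or `NA`.
#' @examples
#' deltaPerDay(100, 150, 50)  # 0.01 per day
#' @export
deltaPerDay <- function(f0, f1, diffDays, epsilon = 1e-12) {
  if (any(diffDays < 1)) stop("diffDays must be >= 1")
  out <- (f1 - f0) / (f0 * diffDays)
  out[!is.finite(out) | abs(f0) <= epsilon] <- NA_real_
  out
}

#' Assemble the modeling feature table
#'
#' Builds the patients-by-features table used for signature modeling:
#' retained F0 columns + retained F1 columns + per-day delta columns for
#' the retained features. Delta columns with more than `maxMissing`
#' missingness are dropped; remaining missing values are imputed with the
#' training-cohort median. Passing a previous [AssembledFeatures-class] as
#' `reference` reuses its medians, epsilons and dropped-column list, so a
#' validation cohort is transformed without leakage.
#'
#' @param featuresF0,featuresF1 data.frames with `patient_id` plus feature
#'   columns named `F0__...` / `F1__...`.
#' @param retained character vector of retained feature names *without*
#'   the timepoint prefix (from [retestFilter()]).
#' @param intervals data.frame with `patient_id` and `diff_days`.
#' @param maxMissing maximum tolerated missing fraction per delta column.
#' @param reference optional training [AssembledFeatures-class].
#' @return an [AssembledFeatures-class].
#' @export
assembleFeatureTable <- function(featuresF0, featuresF1, retained,
                                 intervals, maxMissing = 0.20,
                                 reference = NULL) {
  ids <- Reduce(intersect, list(featuresF0$patient_id,
                                featuresF1$patient_id,
                                intervals$patient_id))
  excluded <- setdiff(union(featuresF0$patient_id, featuresF1$patient_id),
                      ids)
  if (length(excluded))
    message("excluding ", length(excluded),
            " patient(s) missing a timepoint or interval: ",
            paste(head(excluded, 5), collapse = ", "))
  F0 <- featuresF0[match(ids, featuresF0$patient_id), , drop = FALSE]
  F1 <- featuresF1[match(ids, featuresF1$patient_id), , drop = FALSE]
  dd <- intervals$diff_days[match(ids, intervals$patient_id)]

  f0cols <- paste0("F0__", retained)
  f1cols <- paste0("F1__", retained)
  f0cols <- f0cols[f0cols %in% colnames(F0)]
  f1cols <- f1cols[f1cols %in% colnames(F1)]
  tab <- cbind(F0[, f0cols, drop = FALSE], F1[, f1cols, drop = FALSE])

  # epsilon per feature: 1e-8 x cohort median absolute baseline value
  # (training epsilons reused on validation)
  base <- intersect(retained, sub("^F0__", "", f0cols))
  if (is.null(reference)) {
    eps <- vapply(base, function(fn) {
      1e-8 * median(abs(F0[[paste0("F0__", fn)]]), na.rm = TRUE)
    }, numeric(1))
  } else {
    eps <- reference@epsilon
  }

  for (fn in base) {
    d <- deltaPerDay(F0[[paste0("F0__", fn)]], F1[[paste0("F1__", fn)]],
                     dd, epsilon = eps[[fn]])
    tab[[paste0("delta__", fn)]] <- d
  }

  if (is.null(reference)) {
    miss <- vapply(tab, function(x) mean(is.na(x)), numeric(1))
    dropped <- names(miss)[miss > maxMissing]
  } else {
    dropped <- reference@dropped
  }
  tab <- tab[, setdiff(colnames(tab), dropped), drop = FALSE]

  if (is.null(reference)) {
    medians <- vapply(tab, function(x) median(x, na.rm = TRUE), numeric(1))
  } else {
    medians <- reference@medians
  }
  for (cn in colnames(tab)) {
    nas <- is.na(tab[[cn]])
    if (any(nas)) tab[[cn]][nas] <- medians[[cn]]
  }
  new("AssembledFeatures",
      table = cbind(data.frame(patient_id = ids, stringsAsFactors = FALSE),
                    tab),
      medians = medians, epsilon = eps, dropped = dropped)
}
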