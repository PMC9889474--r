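# Random survival forest wrapper (ranger backend, log-rank splits) and
# OOB permutation importance.

#' Fit a random survival forest
#'
#' Trees are grown on bootstrap samples with the log-rank split criterion
#' and `sqrt(p)` candidate features per split. The per-patient risk score is
#' the ensemble mortality: the sum of the ensemble cumulative hazard over
#' the unique event times. Out-of-bag (OOB) mortality and the OOB Harrell C
#' are stored with the model. Deterministic given `seed`.
#'
#' @param X data.frame of numeric features (no missing values).
#' @param time,event survival outcome (months; event = 1 for progression).
#' @param nTrees number of trees (default 500).
#' @param minNodeSize minimal node size (default 6, roughly three events
#'   per terminal node at the cohort's event rate).
#' @param mtry candidate features per split (default `floor(sqrt(p))`).
#' @param importance `"none"` or `"permutation"` (OOB C-index based,
#'   computed by the backend during fitting).
#' @param seed integer seed.
#' @return an [RSFModel-class].
#' @export
fitSurvivalForest <- function(X, time, event, nTrees = 500,
                              minNodeSize = 6, mtry = NULL,
                              importance = c("none", "permutation"),
                              seed = 1) {
  importance <- match.arg(importance)
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(time), length(time) == length(event))
  if (anyNA(X)) stop("X must not contain missing values")
  if (sum(event) == 0) stop("all outcomes are censored; cannot fit")
  if (sum(event) < 20)
    warning("fewer than 20 events; forest estimates will be unstable")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  df <- cbind(data.frame(.time = time, .status = as.integer(event)), X)
  fit <- ranger::ranger(
    formula = survival::Surv(.time, .status) ~ ., data = df,
    num.trees = nTrees, mtry = mtry, min.node.size = minNodeSize,
    splitrule = "logrank", importance = importance,
    keep.inbag = TRUE, seed = seed, num.threads = 1,
    oob.error = TRUE)
  oobMort <- rowSums(fit$chf)
  oobC <- 1 - fit$prediction.error
  new("RSFModel", fit = fit, featureNames = colnames(X),
      oobMortality = oobMort, oobCIndex = oobC,
      params = list(num.trees = nTrees, mtry = mtry,
                    min.node.size = minNodeSize, seed = seed))
}

#' Ensemble mortality for new data
#'
#' @param model an [RSFModel-class].
#' @param X data.frame containing the model's feature columns.
#' @return numeric vector of ensemble mortality (higher = higher risk).
#' @export
predictMortality <- function(model, X) {
  stopifnot(is(model, "RSFModel"))
  missing <- setdiff(model@featureNames, colnames(X))
  if (length(missing))
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  pr <- predict(model@fit, data = X[, model@featureNames, drop = FALSE],
                num.threads = 1)
  rowSums(pr$chf)
}

# OOB ensemble mortality from per-tree predictions and in-bag counts
.oob_mortality <- function(fit, X) {
  pr <- predict(fit, data = X, predict.all = TRUE, num.threads = 1)
  chf <- pr$chf  # n x ntime x ntrees
  mort <- apply(chf, c(1, 3), sum)  # n x ntrees
  inbag <- matrix(unlist(fit$inbag.counts), ncol = fit$num.trees)
  oob <- inbag == 0
  num <- rowSums(mort * oob)
  den <- rowSums(oob)
  ifelse(den > 0, num / den, NA_real_)
}

#' OOB permutation importance of a fitted survival forest
#'
#' Importance of a feature is the mean drop in the out-of-bag Harrell
#' C-index when that feature's column is randomly permuted, over
#' `nRepeats` permutations.
#'
#' @param model an [RSFModel-class] (fitted with `keep.inbag`).
#' @param X,time,event the training data.
#' @param nRepeats permutations per feature.
#' @param seed integer seed.
#' @return named numeric vector of importances.
#' @export
permutationImportance <- function(model, X, time, event, nRepeats = 1,
                                  seed = 1) {
  stopifnot(is(model, "RSFModel"))
  X <- as.data.frame(X)[, model@featureNames, drop = FALSE]
  baseMort <- .oob_mortality(model@fit, X)
  ok <- !is.na(baseMort)
  baseC <- harrellC(baseMort[ok], time[ok], event[ok])$c
  with_seed(seed, {
    imp <- vapply(model@featureNames, function(fn) {
      drops <- vapply(seq_len(nRepeats), function(r) {
        Xp <- X
        Xp[[fn]] <- sample(Xp[[fn]])
        m <- .oob_mortality(model@fit, Xp)
        baseC - harrellC(m[ok], time[ok], event[ok])$c
      }, numeric(1))
      mean(drops)
    }, numeric(1))
    imp
  })
}
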