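# Radiomics signature construction: pool restriction, Boruta selection,
# top-k refit, 0-100 score scaling.

# column filters for the three signature pools
.pool_columns <- function(columns, pool) {
  switch(pool,
    all = columns,
    baseline = columns[startsWith(columns, "F0__")],
    intratumor = columns[grepl("__tumor__", columns, fixed = TRUE)],
    stop("unknown pool: ", pool))
}

#' Build a radiomics signature
#'
#' Restricts the feature table to a pool (`"all"` = every column,
#' `"baseline"` = F0 columns only, `"intratumor"` = tumor-region columns at
#' any timepoint including deltas), runs [borutaSelect()], ranks confirmed
#' features (then tentative ones, if fewer than `k` are confirmed) by final
#' importance with lexicographic tie-breaks, takes the top `k`, and refits
#' a survival forest on those features. The signature score is the
#' ensemble mortality min--max scaled to 0--100 on the training cohort;
#' the scaling parameters are persisted in the model.
#'
#' @param assembled an [AssembledFeatures-class] (or a data.frame with a
#'   `patient_id` column).
#' @param time,event training outcome (months, progression indicator).
#' @param pool `"all"`, `"baseline"` or `"intratumor"`.
#' @param k signature size (default 10).
#' @param nTrees trees for the final forest.
#' @param borutaTrees,maxIter,alpha passed to [borutaSelect()].
#' @param seed integer seed.
#' @return a [SignatureModel-class].
#' @export
buildSignature <- function(assembled, time, event,
                           pool = c("all", "baseline", "intratumor"),
                           k = 10, nTrees = 500, borutaTrees = 300,
                           maxIter = 50, alpha = 0.05, seed = 1) {
  pool <- match.arg(pool)
  tab <- if (is(assembled, "AssembledFeatures")) assembled@table
         else as.data.frame(assembled)
  feats <- setdiff(colnames(tab), "patient_id")
  cols <- .pool_columns(feats, pool)
  if (length(cols) < k)
    stop("pool '", pool, "' yields only ", length(cols),
         " candidates (< k = ", k, ")")
  X <- tab[, cols, drop = FALSE]

  sel <- borutaSelect(X, time, event, maxIter = maxIter, alpha = alpha,
                      nTrees = borutaTrees,
                      seed = stageSeed(seed, paste0("boruta_", pool)))

  orderable <- names(sel@ranking)[names(sel@ranking) %in%
                                    c(sel@confirmed, sel@tentative)]
  if (length(sel@confirmed) >= k) {
    chosen <- orderable[orderable %in% sel@confirmed][seq_len(k)]
  } else if (length(orderable) >= k) {
    chosen <- orderable[seq_len(k)]
  } else {
    warning("only ", length(orderable),
            " decidable features in pool '", pool,
            "'; proceeding with all of them")
    chosen <- orderable
  }
  if (length(chosen) == 0)
    stop("no feature survived selection in pool '", pool, "'")

  forest <- fitSurvivalForest(X[, chosen, drop = FALSE], time, event,
                              nTrees = nTrees,
                              seed = stageSeed(seed, paste0("rsf_", pool)))
  trainMort <- predictMortality(forest, X)
  new("SignatureModel", pool = pool, features = chosen, forest = forest,
      scoreRange = range(trainMort), selection = sel)
}

#' Signature score for new patients
#'
#' Ensemble mortality mapped through the training min--max scaling to the
#' 0--100 signature scale; scores outside the training range are clamped
#' with a warning. Deterministic and monotone in ensemble mortality.
#'
#' @param model a [SignatureModel-class].
#' @param X data.frame containing the model's feature columns (a missing
#'   column is an error naming it).
#' @return numeric scores in \[0, 100\].
#' @export
signatureScore <- function(model, X) {
  stopifnot(is(model, "SignatureModel"))
  mort <- predictMortality(model@forest, X)
  lo <- model@scoreRange[1]; hi <- model@scoreRange[2]
  sc <- if (hi > lo) (mort - lo) / (hi - lo) * 100 else rep(0, length(mort))
  if (any(sc < 0 | sc > 100))
    warning(sum(sc < 0 | sc > 100),
            " score(s) outside the training range were clamped to [0, 100]")
  pmin(pmax(sc, 0), 100)
}
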