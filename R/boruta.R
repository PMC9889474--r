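# All-relevant feature selection by shadow comparison ("Boruta") wrapped
# around the random survival forest.

#' Boruta feature selection around a random survival forest
#'
#' Each iteration appends a shadow (independently permuted copy) of every
#' still-active candidate, fits a survival forest with OOB permutation
#' importance, and scores a "hit" for every candidate whose importance
#' exceeds the maximum shadow importance. After each iteration two-sided
#' binomial tests (p = 0.5, Bonferroni-corrected over the initial candidate
#' count) confirm (upper tail) or reject (lower tail) candidates at
#' `alpha`; rejected candidates are removed from subsequent iterations.
#' The loop ends when every candidate is decided or after `maxIter`
#' iterations; undecided candidates remain `tentative`, ordered in the
#' final ranking by their median importance relative to the median
#' max-shadow importance.
#'
#' @param X data.frame of candidate features (>= 2 columns, no missing
#'   values).
#' @param time,event survival outcome.
#' @param maxIter maximum iterations (>= 5; default 100).
#' @param alpha significance level of the binomial decisions.
#' @param nTrees trees per iteration forest.
#' @param seed integer seed (iteration seeds are derived from it).
#' @return a [SelectionResult-class].
#' @export
borutaSelect <- function(X, time, event, maxIter = 100, alpha = 0.05,
                         nTrees = 300, seed = 1) {
  X <- as.data.frame(X)
  if (ncol(X) < 2) stop("need at least 2 candidate features")
  if (maxIter < 5) stop("maxIter < 5: binomial test is powerless")
  candidates <- colnames(X)
  m <- length(candidates)
  active <- candidates          # not yet rejected
  confirmed <- character(0)
  rejected <- character(0)
  hits <- setNames(integer(m), candidates)
  tested <- setNames(integer(m), candidates)
  hist <- matrix(NA_real_, nrow = maxIter, ncol = m,
                 dimnames = list(NULL, candidates))
  shadowMax <- rep(NA_real_, maxIter)

  iter <- 0L
  while (iter < maxIter && length(setdiff(active, confirmed)) > 0) {
    iter <- iter + 1L
    itSeed <- stageSeed(seed, paste0("boruta_iter_", iter))
    shadows <- with_seed(itSeed, {
      sh <- as.data.frame(lapply(X[active], sample))
      colnames(sh) <- paste0(".shadow_", seq_along(active))
      sh
    })
    fit <- fitSurvivalForest(cbind(X[active], shadows), time, event,
                             nTrees = nTrees, importance = "permutation",
                             seed = itSeed)
    imp <- fit@fit$variable.importance
    shadowImp <- imp[startsWith(names(imp), ".shadow_")]
    featImp <- imp[active]
    shadowMax[iter] <- max(shadowImp)
    hist[iter, active] <- featImp

    hit <- featImp > shadowMax[iter]
    hits[active] <- hits[active] + as.integer(hit)
    tested[active] <- tested[active] + 1L

    undecided <- setdiff(active, confirmed)
    pHi <- pbinom(hits[undecided] - 1L, tested[undecided], 0.5,
                  lower.tail = FALSE)
    pLo <- pbinom(hits[undecided], tested[undecided], 0.5)
    newConf <- undecided[pHi < alpha / m]
    newRej <- undecided[pLo < alpha / m]
    confirmed <- c(confirmed, newConf)
    rejected <- c(rejected, newRej)
    active <- setdiff(active, newRej)
    if (length(active) < 2) break  # nothing left to shadow against
  }

  hist <- hist[seq_len(iter), , drop = FALSE]
  shadowMax <- shadowMax[seq_len(iter)]
  tentative <- setdiff(candidates, c(confirmed, rejected))

  medImp <- apply(hist, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col)) median(col) else -Inf
  })
  # ranking: confirmed first, then tentative (those beating the median
  # shadow ceiling ahead of those that do not), then rejected; within each
  # block by median importance, ties broken by name.
  medShadow <- median(shadowMax, na.rm = TRUE)
  block <- ifelse(candidates %in% confirmed, 0L,
           ifelse(candidates %in% tentative,
                  ifelse(medImp[candidates] > medShadow, 1L, 2L), 3L))
  ord <- order(block, -medImp[candidates], candidates)
  ranking <- setNames(medImp[candidates][ord], candidates[ord])

  new("SelectionResult", confirmed = confirmed, rejected = rejected,
      tentative = tentative, importanceHistory = hist,
      shadowMaxHistory = shadowMax, ranking = ranking,
      nIter = iter)
}
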