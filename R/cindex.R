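# Harrell's concordance index and the paired bootstrap model comparison.

#' Harrell's concordance index
#'
#' Comparable pairs are those where the shorter observed time is an event
#' and the times differ; a pair is concordant when the shorter-lived
#' patient has the higher risk, with ties in risk receiving 0.5 credit.
#' The confidence interval is a percentile bootstrap over patients.
#'
#' @param risk numeric risk scores (higher = earlier expected event).
#' @param time,event survival outcome.
#' @param nBoot bootstrap resamples for the CI (0 to skip).
#' @param seed integer seed for the bootstrap.
#' @return a list with `c`, `ci` (length-2, or NULL) and `n_comparable`.
#' @examples
#' harrellC(c(3, 2, 1), time = c(1, 2, 3), event = c(1, 1, 1))$c  # 1
#' @export
harrellC <- function(risk, time, event, nBoot = 0, seed = 1) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  cval <- .harrell_c_cpp(as.numeric(risk), as.numeric(time),
                         as.integer(event))
  if (is.na(cval)) stop("no comparable pairs")
  ci <- NULL
  if (nBoot > 0) {
    bs <- with_seed(seed, .harrell_c_boot_cpp(as.numeric(risk),
                                              as.numeric(time),
                                              as.integer(event),
                                              as.integer(nBoot)))
    ci <- unname(quantile(bs, c(0.025, 0.975), na.rm = TRUE))
  }
  comp <- 0
  for (i in seq_along(time)) {
    if (event[i]) comp <- comp + sum(time > time[i])
  }
  list(c = cval, ci = ci, n_comparable = comp)
}

#' Paired nonparametric comparison of two concordance indices
#'
#' Paired patient-level bootstrap of `deltaC = C(risk1) - C(risk2)`: the
#' same resample is applied to both risk scores, and the two-sided p-value
#' is `2 * min(P(deltaC* <= 0), P(deltaC* >= 0))` with the `(+1)/(n+1)`
#' small-sample correction, capped at 1. When the bootstrap distribution
#' is degenerate at 0 (identical scores) the p-value is 1 by convention.
#'
#' @param risk1,risk2 risk scores for the same patients.
#' @param time,event survival outcome.
#' @param nBoot bootstrap resamples (default 2000).
#' @param seed integer seed.
#' @return a list with `p`, `delta_c` (observed difference) and `boot`
#'   (the bootstrap draws).
#' @export
compareCPaired <- function(risk1, risk2, time, event, nBoot = 2000,
                           seed = 1) {
  stopifnot(length(risk1) == length(risk2),
            length(risk1) == length(time))
  d0 <- .harrell_c_cpp(as.numeric(risk1), as.numeric(time),
                       as.integer(event)) -
        .harrell_c_cpp(as.numeric(risk2), as.numeric(time),
                       as.integer(event))
  bs <- with_seed(seed, .compare_c_boot_cpp(as.numeric(risk1),
                                            as.numeric(risk2),
                                            as.numeric(time),
                                            as.integer(event),
                                            as.integer(nBoot)))
  bs <- bs[!is.na(bs)]
  if (length(bs) == 0 || all(bs == 0))
    return(list(p = 1.0, delta_c = d0, boot = bs))
  pLe <- (1 + sum(bs <= 0)) / (length(bs) + 1)
  pGe <- (1 + sum(bs >= 0)) / (length(bs) + 1)
  list(p = min(1, 2 * min(pLe, pGe)), delta_c = d0, boot = bs)
}
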