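# Maximally selected log-rank cutoff, Kaplan-Meier groups, log-rank test.

#' Maximally selected log-rank cutoff
#'
#' Evaluates the two-sample log-rank chi-square at every observed score
#' within the quantile range (group = score > cutoff) and returns the
#' cutoff maximizing the statistic; exact ties are broken toward the
#' median score. The full candidate profile is returned for plotting. The
#' plain log-rank p-value on the induced split is anti-conservative after
#' maximal selection; [stratifyAndReport()] adds a permutation-adjusted p.
#'
#' @param scores signature scores.
#' @param time,event survival outcome (>= 20 patients, >= 10 events).
#' @param quantileRange candidate range as score quantiles (default
#'   `c(0.10, 0.90)` to avoid degenerate groups).
#' @return a [StratificationResult-class] (without permutation p).
#' @export
maxstatCutoff <- function(scores, time, event,
                          quantileRange = c(0.10, 0.90)) {
  stopifnot(length(scores) == length(time))
  if (length(scores) < 20) stop("need >= 20 patients")
  if (sum(event) < 10) stop("need >= 10 events")
  qr <- quantile(scores, quantileRange)
  cand <- sort(unique(scores[scores >= qr[1] & scores <= qr[2]]))
  # a cutoff equal to the largest candidate leaves the upper group empty
  cand <- cand[cand < max(scores)]
  if (length(cand) == 0) stop("no candidate cutoff within quantile range")
  stat <- .logrank_profile_cpp(as.numeric(time), as.integer(event),
                               as.numeric(scores), as.numeric(cand))
  best <- which(stat == max(stat))
  if (length(best) > 1) {
    med <- median(scores)
    best <- best[which.min(abs(cand[best] - med))]
  }
  cutoff <- cand[best]
  groups <- factor(ifelse(scores > cutoff, "rapid", "slow"),
                   levels = c("rapid", "slow"))
  med <- .km_median_by_group(time, event, groups)
  lr <- logrankTest(time, event, groups)
  new("StratificationResult", cutoff = cutoff, groups = groups,
      profile = data.frame(cutoff = cand, statistic = stat),
      medianPFS = med,
      logrank = c(statistic = lr$statistic, p = lr$p))
}

# median = first time S(t) <= 0.5 (right-continuous step convention);
# NA when the curve never reaches 0.5
.km_median_by_group <- function(time, event, groups) {
  vapply(levels(groups), function(g) {
    idx <- groups == g
    if (!any(idx)) return(NA_real_)
    sf <- survival::survfit(survival::Surv(time[idx], event[idx]) ~ 1)
    hit <- sf$surv <= 0.5 + 1e-12
    if (!any(hit)) NA_real_ else min(sf$time[hit])
  }, numeric(1))
}

#' Kaplan-Meier estimates per group
#'
#' Product-limit estimator with censoring; the median is the first time at
#' which the survival curve drops to 0.5 or below (right-continuous step
#' convention), or `NA` if the curve never reaches 0.5.
#'
#' @param time,event survival outcome.
#' @param groups factor of group labels (nonempty groups).
#' @return a list with `fit` (a `survfit` object over groups), `median`
#'   (named per-group median PFS) and `curves` (data.frame: group, time,
#'   surv).
#' @export
kmEstimate <- function(time, event, groups) {
  groups <- droplevels(as.factor(groups))
  stopifnot(length(time) == length(groups), nlevels(groups) >= 1)
  df <- data.frame(.time = time, .status = as.integer(event),
                   group = groups)
  fit <- survival::survfit(survival::Surv(.time, .status) ~ group,
                           data = df)
  med <- .km_median_by_group(time, event, groups)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(groups)[1], length(sm$time))
         else sub("^group=", "", as.character(sm$strata))
  list(fit = fit, median = med,
       curves = data.frame(group = grp, time = sm$time, surv = sm$surv))
}

#' Two-sample log-rank test
#'
#' Standard log-rank chi-square with 1 degree of freedom via
#' `survival::survdiff`.
#'
#' @param time,event survival outcome.
#' @param groups factor with exactly 2 nonempty levels.
#' @return a list with `statistic` and `p`.
#' @export
logrankTest <- function(time, event, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2)
    stop("log-rank test requires exactly 2 nonempty groups")
  df <- data.frame(.time = time, .status = as.integer(event),
                   group = groups)
  sd <- survival::survdiff(survival::Surv(.time, .status) ~ group,
                           data = df)
  list(statistic = unname(sd$chisq),
       p = unname(1 - pchisq(sd$chisq, df = 1)))
}
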