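# Clinical Cox baselines, forward-AIC model selection, and the combined
# clinico-radiomics model. All Cox fits use Efron tie handling.

# one Cox fit -> tidy list
.cox_tidy <- function(fit, flagged = FALSE) {
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  list(terms = rownames(co),
       coef = co[, "coef"],
       hr = co[, "exp(coef)"],
       ci_lower = ci[, "lower .95"],
       ci_upper = ci[, "upper .95"],
       p = co[, "Pr(>|z|)"],
       loglik = fit$loglik[length(fit$loglik)],
       aic = AIC(fit),
       flagged = flagged,
       fit = fit)
}

#' Univariate Cox regression
#'
#' Partial-likelihood fit (Efron ties) of one covariate against the
#' outcome; categorical covariates are expanded against their first factor
#' level as the reference. Non-convergence, complete separation or a
#' constant covariate yield a flagged result rather than an error.
#'
#' @param covariate numeric or factor covariate.
#' @param time,event survival outcome.
#' @param name covariate label for the output.
#' @return a list with terms, coefficients, hazard ratios, 95% Wald CIs,
#'   p-values, log-likelihood and AIC; `flagged = TRUE` marks a degenerate
#'   fit (with HR undefined).
#' @export
coxUnivariate <- function(covariate, time, event, name = "x") {
  df <- data.frame(.time = time, .status = as.integer(event),
                   x = covariate)
  names(df)[3] <- name
  if (length(unique(df[[name]][!is.na(df[[name]])])) < 2)
    return(list(terms = name, coef = NA_real_, hr = NA_real_,
                ci_lower = NA_real_, ci_upper = NA_real_, p = NA_real_,
                loglik = NA_real_, aic = NA_real_, flagged = TRUE,
                fit = NULL))
  fml <- stats::as.formula(paste0("survival::Surv(.time, .status) ~ `",
                                  name, "`"))
  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph(fml, data = df, ties = "efron"),
      warning = function(w) {
        if (grepl("converge|infinite", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(coef(fit))) ||
      any(abs(coef(fit)) > 20))
    return(list(terms = name, coef = NA_real_, hr = NA_real_,
                ci_lower = NA_real_, ci_upper = NA_real_, p = NA_real_,
                loglik = NA_real_, aic = NA_real_, flagged = TRUE,
                fit = fit))
  .cox_tidy(fit)
}

#' Forward selection of a multivariate Cox model by AIC
#'
#' Starts from the null model and greedily adds the covariate giving the
#' largest AIC decrease, stopping when no addition lowers the AIC; among
#' AIC ties the model with fewer parameters is preferred (i.e. the
#' candidate is not added). Covariates whose fit fails are skipped with a
#' message.
#'
#' @param covariates data.frame of candidate covariates.
#' @param time,event survival outcome.
#' @return a list as in [coxUnivariate()] plus `selected` (character,
#'   possibly empty for the null model) and `aic_null`.
#' @export
coxForwardAIC <- function(covariates, time, event) {
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) < 2)
    stop("need at least 2 candidate covariates")
  df <- cbind(data.frame(.time = time, .status = as.integer(event)),
              covariates)
  nullFit <- survival::coxph(survival::Surv(.time, .status) ~ 1, data = df,
                             ties = "efron")
  aicBest <- AIC(nullFit)
  selected <- character(0)
  remaining <- colnames(covariates)
  bestFit <- nullFit
  repeat {
    gains <- vapply(remaining, function(cn) {
      fml <- stats::as.formula(paste0(
        "survival::Surv(.time, .status) ~ ",
        paste0("`", c(selected, cn), "`", collapse = " + ")))
      fit <- tryCatch(survival::coxph(fml, data = df, ties = "efron"),
                      error = function(e) NULL)
      if (is.null(fit) || any(!is.finite(coef(fit)))) return(NA_real_)
      AIC(fit)
    }, numeric(1))
    gains <- gains[!is.na(gains)]
    if (length(gains) == 0) break
    best <- names(gains)[which.min(gains)]
    # strict improvement required beyond ties (< 1e-6): prefer fewer params
    if (min(gains) < aicBest - 1e-6) {
      selected <- c(selected, best)
      remaining <- setdiff(remaining, best)
      aicBest <- min(gains)
      fml <- stats::as.formula(paste0(
        "survival::Surv(.time, .status) ~ ",
        paste0("`", selected, "`", collapse = " + ")))
      bestFit <- survival::coxph(fml, data = df, ties = "efron")
      if (length(remaining) == 0) break
    } else break
  }
  out <- if (length(selected) == 0)
    list(terms = character(0), coef = numeric(0), hr = numeric(0),
         ci_lower = numeric(0), ci_upper = numeric(0), p = numeric(0),
         loglik = nullFit$loglik[1], aic = AIC(nullFit), flagged = FALSE,
         fit = nullFit)
  else .cox_tidy(bestFit)
  out$selected <- selected
  out$aic_null <- AIC(nullFit)
  out
}

#' Combined clinico-radiomics Cox model
#'
#' Cox fit on the signature score plus the selected clinical covariates;
#' the patient-level risk is the linear predictor.
#'
#' @param scores numeric signature scores (aligned with the covariates by
#'   row).
#' @param clinical data.frame of the selected clinical covariates (may
#'   have zero columns).
#' @param time,event survival outcome.
#' @return a list as in [coxUnivariate()] plus `risk` (linear predictor).
#' @export
combineClinicoRadiomics <- function(scores, clinical, time, event) {
  clinical <- as.data.frame(clinical)
  stopifnot(length(scores) == length(time),
            nrow(clinical) == 0 || nrow(clinical) == length(time))
  df <- data.frame(.time = time, .status = as.integer(event),
                   signature = scores)
  if (ncol(clinical) > 0) df <- cbind(df, clinical)
  fml <- stats::as.formula(paste0(
    "survival::Surv(.time, .status) ~ ",
    paste0("`", c("signature", colnames(clinical)), "`",
           collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  out <- .cox_tidy(fit)
  out$risk <- unname(predict(fit, type = "lp"))
  out
}
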