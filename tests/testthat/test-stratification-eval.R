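# Maxstat cutoff search, KM estimates, log-rank test, time-dependent ROC.

make_threshold_cohort <- function(n, cut = 50, hr = 3, seed = 1) {
  withr::with_seed(seed, {
    sc <- runif(n, 0, 100)
    rate <- 0.08 * ifelse(sc > cut, hr, 1)
    t <- rexp(n, rate); cc <- runif(n, 0, 60)
    list(scores = sc, time = pmin(t, cc), event = as.integer(t <= cc))
  })
}

test_that("maxstat: profile equals survdiff at every candidate and the
           returned statistic is the exhaustive maximum", {
  d <- make_threshold_cohort(120, seed = 5)
  res <- maxstatCutoff(d$scores, d$time, d$event)
  prof <- res@profile
  idx <- sample(nrow(prof), 15)
  for (i in idx) {
    ref <- survival::survdiff(
      survival::Surv(d$time, d$event) ~ I(d$scores > prof$cutoff[i]))
    expect_equal(prof$statistic[i], unname(ref$chisq), tolerance = 1e-9)
  }
  expect_true(all(max(prof$statistic) >= prof$statistic))
  expect_equal(prof$statistic[prof$cutoff == res@cutoff],
               max(prof$statistic))
  expect_true(all(levels(res@groups) == c("rapid", "slow")))
  expect_gt(sum(res@groups == "rapid"), 0)
  expect_gt(sum(res@groups == "slow"), 0)
})

test_that("maxstat recovers a planted threshold and is invariant to
           monotone score transforms", {
  hits <- 0
  for (s in 1:8) {
    d <- make_threshold_cohort(300, cut = 50, hr = 3, seed = s)
    res <- maxstatCutoff(d$scores, d$time, d$event)
    if (abs(res@cutoff - 50) <= 7.5) hits <- hits + 1
    # rank-preserving transform gives the same patient partition
    res2 <- maxstatCutoff(qnorm(d$scores / 100.0001), d$time, d$event)
    expect_identical(res@groups, res2@groups)
  }
  expect_gte(hits, 6)
})

test_that("maxstat input validation", {
  d <- make_threshold_cohort(15, seed = 2)
  expect_error(maxstatCutoff(d$scores, d$time, d$event), ">= 20")
})

test_that("KM estimate: step-convention median, all-censored curves and
           brute-force product-limit equality", {
  g <- factor(rep("one", 10))
  km <- kmEstimate(1:10, rep(1, 10), g)
  expect_equal(unname(km$median["one"]), 5)  # first time S(t) <= 0.5

  kmC <- kmEstimate(1:10, rep(0, 10), g)
  expect_true(all(kmC$curves$surv == 1))
  expect_true(is.na(kmC$median["one"]))

  for (s in 1:10) {
    withr::with_seed(s, {
      n <- 15
      t <- sample(1:20, n, TRUE); e <- rbinom(n, 1, 0.7)
      km2 <- kmEstimate(t, e, factor(rep("g", n)))
      # brute-force product over event times
      ut <- sort(unique(t[e == 1]))
      surv <- cumprod(vapply(ut, function(u) {
        atRisk <- sum(t >= u); d <- sum(t == u & e == 1)
        1 - d / atRisk
      }, numeric(1)))
      got <- vapply(ut, function(u) {
        min(km2$curves$surv[km2$curves$time <= u])
      }, numeric(1))
      expect_equal(got, surv, tolerance = 1e-12)
    })
  }
})

test_that("log-rank test: symmetry under label swap, nominal type-I error
           and power under hazard ratio 3", {
  withr::with_seed(7, {
    t <- rexp(100, 0.1); e <- rbinom(100, 1, 0.8)
    g <- factor(rep(c("a", "b"), 50))
    g2 <- factor(ifelse(g == "a", "b", "a"))
    expect_equal(logrankTest(t, e, g)$statistic,
                 logrankTest(t, e, g2)$statistic)
    expect_error(logrankTest(t, e, factor(rep("a", 100))), "2")
  })
  rej <- 0; nsim <- 200
  for (s in 1:nsim) {
    withr::with_seed(s + 2000, {
      t <- rexp(200, 0.1); cc <- runif(200, 0, 40)
      g <- factor(rep(c("a", "b"), 100))
      p <- logrankTest(pmin(t, cc), as.integer(t <= cc), g)$p
      if (p < 0.05) rej <- rej + 1
    })
  }
  expect_gte(rej / nsim, 0.02)
  expect_lte(rej / nsim, 0.09)
  power <- 0
  for (s in 1:20) {
    withr::with_seed(s + 3000, {
      g <- rep(0:1, 100)
      t <- rexp(200, 0.08 * ifelse(g == 1, 3, 1))
      p <- logrankTest(t, rep(1, 200), factor(g))$p
      if (p < 0.05) power <- power + 1
    })
  }
  expect_gte(power / 20, 0.95)
})

test_that("time-dependent AUC: perfect marker scores 1 at every horizon,
           null markers hover at 0.5, and the censoring-free case equals
           the Mann-Whitney AUC", {
  withr::with_seed(17, {
    n <- 200
    t <- rexp(n, 1 / 12)
    perfect <- -t
    res <- timeDependentAUC(perfect, t, rep(1, n), nBoot = 0)
    expect_equal(res$auc, rep(1, 3))

    sc <- rnorm(n)
    resN <- timeDependentAUC(sc, t, rep(1, n), nBoot = 0)
    expect_true(all(abs(resN$auc - 0.5) < 0.12))

    # no censoring before horizon: reduction to plain Mann-Whitney
    h <- 9
    cases <- which(t <= h); controls <- which(t > h)
    mw <- mean(outer(sc[cases], sc[controls], function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(resN$auc[resN$horizon == h], mw, tolerance = 1e-12)
  })
})

test_that("tdROC AUC is invariant to monotone score transforms and
           validates its horizons", {
  withr::with_seed(23, {
    n <- 150
    t <- rexp(n, 1 / 12); cc <- runif(n, 0, 40)
    time <- pmin(t, cc); ev <- as.integer(t <= cc)
    sc <- runif(n, 1, 99)
    a1 <- timeDependentAUC(sc, time, ev, nBoot = 0)
    a2 <- timeDependentAUC(log(sc), time, ev, nBoot = 0)
    expect_equal(a1$auc, a2$auc, tolerance = 1e-12)
    expect_error(timeDependentAUC(sc, time, ev, horizons = 1e5,
                                  nBoot = 0), "follow-up")
  })
})

test_that("stratify-and-report: training cutoff applied unchanged to
           validation and regeneration is identical", {
  dT <- make_threshold_cohort(150, seed = 41)
  dV <- make_threshold_cohort(60, seed = 42)
  out <- tempfile()
  res <- stratifyAndReport(dT$scores, dT$time, dT$event,
                           dV$scores, dV$time, dV$event,
                           nPermutations = 50, nBoot = 50,
                           outDir = out, seed = 4)
  expect_true(file.exists(file.path(out, "report.json")))
  expect_true(file.exists(file.path(out, "km_train.png")))
  expect_identical(
    res$valid$groups,
    factor(ifelse(dV$scores > res$train@cutoff, "rapid", "slow"),
           levels = c("rapid", "slow")))
  res2 <- stratifyAndReport(dT$scores, dT$time, dT$event,
                            dV$scores, dV$time, dV$event,
                            nPermutations = 50, nBoot = 50,
                            outDir = NULL, seed = 4)
  expect_identical(res$report$cutoff, res2$report$cutoff)
  expect_identical(res$report$train, res2$report$train)
  # rapid group progresses faster in both cohorts (planted direction)
  expect_lt(res$report$train$median_pfs_rapid,
            res$report$train$median_pfs_slow)
  expect_lt(res$report$valid$median_pfs_rapid,
            res$report$valid$median_pfs_slow)
})
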