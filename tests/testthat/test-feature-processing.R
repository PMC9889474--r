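# ICC reproducibility filtering, per-day deltas, table assembly.

test_that("ICC: identical measurements give 1, offsets are penalized under
           absolute agreement, independent noise stays low", {
  x <- rnorm(30)
  expect_equal(computeICC(x, x), 1.0)

  # constructed 5-point example with a large constant offset: closed-form
  # mean squares give ICC far below 1 under absolute agreement
  a <- c(1, 2, 3, 4, 5)
  icc_off <- computeICC(a, a + 10)
  expect_lt(icc_off, 0.2)
  # oracle from the mean-squares decomposition computed directly
  n <- 5; k <- 2
  xm <- (a + a + 10) / 2; grand <- mean(c(a, a + 10))
  msr <- k * sum((xm - grand)^2) / (n - 1)
  msc <- n * sum((c(mean(a), mean(a + 10)) - grand)^2) / (k - 1)
  sse <- sum((c(a, a + 10) - grand)^2) - k * sum((xm - grand)^2) -
    n * sum((c(mean(a), mean(a + 10)) - grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  expect_equal(icc_off, oracle, tolerance = 1e-12)

  # under the null, |ICC| is small in nearly all replicates
  hits <- 0
  for (s in 1:300) {
    withr::with_seed(s, {
      if (abs(computeICC(rnorm(30), rnorm(30))) < 0.4) hits <- hits + 1
    })
  }
  expect_gte(hits / 300, 0.95)

  expect_equal(computeICC(rep(2, 10), rep(2, 10)), 1.0)  # zero variance
  expect_error(computeICC(1:2, 2:3), "at least 3")
})

test_that("retest filter: exact copy retains everything, a noise-replaced
           feature is excluded, impossible thresholds retain nothing", {
  withr::with_seed(5, {
    tab <- data.frame(patient_id = sprintf("p%02d", 1:30),
                      a = rnorm(30, 10, 4), b = runif(30), c = rnorm(30))
    expect_setequal(retestFilter(tab, tab)$retained, c("a", "b", "c"))
    expect_length(retestFilter(tab, tab, threshold = 1.01)$retained, 0)
  })
  excl <- 0
  for (s in 1:100) {
    withr::with_seed(s, {
      tab <- data.frame(patient_id = sprintf("p%02d", 1:30),
                        a = rnorm(30, 10, 4), b = runif(30))
      ret <- tab
      ret$b <- runif(30)  # fresh noise for b
      out <- retestFilter(tab, ret)
      if (!("b" %in% out$retained)) excl <- excl + 1
    })
  }
  expect_gte(excl / 100, 0.95)

  bad <- data.frame(patient_id = "p1", z = 1)
  good <- data.frame(patient_id = "p1", a = 1)
  expect_error(retestFilter(good, bad), "mismatch.*z|z.*mismatch")
})

test_that("per-day delta: printed example, zero change, near-zero guard
           and argument validation", {
  expect_equal(deltaPerDay(100, 150, 50), 0.01)
  expect_equal(deltaPerDay(7, 7, 123), 0)
  expect_true(is.na(deltaPerDay(0, 5, 10)))
  expect_error(deltaPerDay(1, 2, 0.5), ">= 1")
})

test_that("delta identities: swap antisymmetry and scale invariance on
           random triples", {
  withr::with_seed(9, {
    for (i in 1:200) {
      f0 <- runif(1, 0.5, 100); f1 <- runif(1, 0.5, 100)
      dd <- sample(1:120, 1)
      d01 <- deltaPerDay(f0, f1, dd)
      d10 <- deltaPerDay(f1, f0, dd)
      expect_equal(d01, -d10 * (f1 / f0), tolerance = 1e-12)
      cc <- runif(1, 0.1, 10)
      expect_equal(deltaPerDay(cc * f0, cc * f1, dd), d01,
                   tolerance = 1e-12)
    }
  })
})

test_that("filter monotonicity: raising the ICC threshold never enlarges
           the retained set", {
  withr::with_seed(14, {
    tab <- data.frame(patient_id = sprintf("p%02d", 1:30))
    ret <- tab
    for (j in 1:15) {
      x <- rnorm(30)
      tab[[paste0("f", j)]] <- x
      ret[[paste0("f", j)]] <- x + rnorm(30, sd = runif(1, 0.05, 2))
    }
    prev <- NULL
    for (thr in c(0.5, 0.7, 0.8, 0.9, 0.99)) {
      cur <- retestFilter(tab, ret, threshold = thr)$retained
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
  })
})

test_that("table assembly: column arity, training-median imputation is
           reused on validation (no leakage)", {
  withr::with_seed(3, {
    mk <- function(ids, tag, a, b) {
      df <- data.frame(patient_id = ids)
      df[[paste0(tag, "__tumor__first_order__mean")]] <- a
      df[[paste0(tag, "__tumor__shape__voxel_volume")]] <- b
      df
    }
    idsT <- sprintf("t%02d", 1:10)
    f0 <- mk(idsT, "F0", rnorm(10, 50), rnorm(10, 1000))
    f1 <- mk(idsT, "F1", rnorm(10, 55), rnorm(10, 1100))
    iv <- data.frame(patient_id = idsT, diff_days = sample(16:90, 10))
    retained <- c("tumor__first_order__mean",
                  "tumor__shape__voxel_volume")
    asm <- assembleFeatureTable(f0, f1, retained, iv)
    expect_equal(ncol(asm@table), 1 + 3 * 2)  # id + F0 + F1 + delta
    expect_false(anyNA(asm@table))

    # validation with a missing (near-zero f0) value imputed by the
    # *training* median, not the validation median
    idsV <- sprintf("v%02d", 1:6)
    f0v <- mk(idsV, "F0", c(0, rnorm(5, 500)), rnorm(6, 1000))
    f1v <- mk(idsV, "F1", rnorm(6, 505), rnorm(6, 1100))
    ivv <- data.frame(patient_id = idsV, diff_days = rep(30, 6))
    asmV <- assembleFeatureTable(f0v, f1v, retained, ivv,
                                 reference = asm)
    dcol <- "delta__tumor__first_order__mean"
    imputed <- asmV@table[[dcol]][1]
    validMedian <- median(asmV@table[[dcol]][-1])
    expect_equal(imputed, asm@medians[[dcol]])
    expect_false(isTRUE(all.equal(imputed, validMedian)))
  })
})

test_that("patients missing a timepoint are excluded with a message", {
  f0 <- data.frame(patient_id = c("a", "b"), F0__x = c(1, 2))
  f1 <- data.frame(patient_id = "a", F1__x = 3)
  iv <- data.frame(patient_id = c("a", "b"), diff_days = c(30, 40))
  expect_message(asm <- assembleFeatureTable(f0, f1, "x", iv),
                 "excluding")
  expect_equal(asm@table$patient_id, "a")
})
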