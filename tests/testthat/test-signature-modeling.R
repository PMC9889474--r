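# Survival forest, permutation importance, Boruta selection, signatures.

test_that("survival forest: perfectly informative feature gives high OOB C,
           pure noise stays near 0.5, seeds give identical fits", {
  withr::with_seed(31, {
    t <- rexp(300, 0.1); e <- rep(1L, 300)
    m <- fitSurvivalForest(data.frame(perfect = -t), t, e, nTrees = 300,
                           seed = 7)
    expect_gte(m@oobCIndex, 0.95)
    m2 <- fitSurvivalForest(data.frame(perfect = -t), t, e, nTrees = 300,
                            seed = 7)
    expect_identical(m@oobMortality, m2@oobMortality)
  })
  cs <- vapply(1:8, function(s) {
    d <- planted_survival(200, 10, seed = s)
    fitSurvivalForest(d$X, d$time, d$event, nTrees = 300,
                      seed = s)@oobCIndex
  }, numeric(1))
  expect_gte(mean(cs > 0.40 & cs < 0.60), 0.9)
})

test_that("survival forest rejects missing values and all-censored
           outcomes", {
  X <- data.frame(a = c(1, NA, 3))
  expect_error(fitSurvivalForest(X, 1:3, c(1, 1, 0)), "missing")
  X2 <- data.frame(a = rnorm(30))
  expect_error(fitSurvivalForest(X2, rexp(30), rep(0L, 30)), "censored")
})

test_that("permutation importance: planted feature dominates, constant
           columns score zero", {
  withr::with_seed(12, {
    n <- 250
    t <- rexp(n, 0.1); e <- rbinom(n, 1, 0.9)
    X <- data.frame(planted = -t, noise = rnorm(n), flat = rep(1, n))
    m <- fitSurvivalForest(X, t, e, nTrees = 200, seed = 3)
    imp <- permutationImportance(m, X, t, e, nRepeats = 2, seed = 5)
    expect_equal(names(which.max(imp)), "planted")
    expect_equal(unname(imp["flat"]), 0)
    expect_gt(imp[["planted"]], 10 * abs(imp[["noise"]]))
  })
})

test_that("Boruta: copies of one noise vector confirm nothing and the
           result is deterministic under a fixed seed", {
  withr::with_seed(40, {
    z <- rnorm(120)
    X <- as.data.frame(replicate(6, z))
    colnames(X) <- paste0("c", 1:6)
    t <- rexp(120, 0.1); e <- rbinom(120, 1, 0.85)
    sel <- borutaSelect(X, t, e, maxIter = 15, nTrees = 150, seed = 2)
    expect_length(sel@confirmed, 0)
    sel2 <- borutaSelect(X, t, e, maxIter = 15, nTrees = 150, seed = 2)
    expect_identical(sel@confirmed, sel2@confirmed)
    expect_identical(sel@ranking, sel2@ranking)
    expect_setequal(c(sel@confirmed, sel@rejected, sel@tentative),
                    colnames(X))
  })
  expect_error(borutaSelect(data.frame(a = 1:9, b = 9:1),
                            rexp(9), rep(1L, 9), maxIter = 3),
               "powerless")
})

test_that("Boruta recovers planted features against noise", {
  d <- planted_survival(200, 30, informative = 1:4, beta = 1.0,
                        seed = 77)
  sel <- borutaSelect(d$X, d$time, d$event, maxIter = 25, nTrees = 200,
                      seed = 5)
  expect_gte(sum(sprintf("f%02d", 1:4) %in% sel@confirmed), 3)
  expect_lte(sum(setdiff(colnames(d$X), sprintf("f%02d", 1:4)) %in%
                   sel@confirmed), 2)
})

test_that("signature pools restrict the candidate columns correctly", {
  cols <- c("F0__tumor__glcm__contrast", "F0__peri5__glcm__contrast",
            "F1__tumor__glcm__contrast", "F1__peri10__glrlm__sre",
            "delta__tumor__first_order__mean",
            "delta__peri5__first_order__mean")
  base <- DeltaRadiomics:::.pool_columns(cols, "baseline")
  expect_true(all(startsWith(base, "F0__")))
  intra <- DeltaRadiomics:::.pool_columns(cols, "intratumor")
  expect_true(all(grepl("__tumor__", intra)))
  expect_false(any(grepl("peri", intra)))
  expect_identical(DeltaRadiomics:::.pool_columns(cols, "all"), cols)
})

test_that("signature scores: training endpoints map to 0/100, duplicates
           score identically, held-out scores track the planted risk", {
  d <- planted_survival(180, 12, informative = 1:3, beta = 1.2, seed = 55)
  colnames(d$X) <- c(paste0("F0__tumor__first_order__f", 1:6),
                     paste0("delta__tumor__first_order__f", 1:6))
  tab <- cbind(data.frame(patient_id = sprintf("p%03d", 1:180)), d$X)
  sig <- suppressWarnings(
    buildSignature(tab, d$time, d$event, pool = "all", k = 5,
                   nTrees = 200, borutaTrees = 150, maxIter = 15,
                   seed = 9))
  expect_lte(length(sig@features), 5)
  sc <- signatureScore(sig, tab)
  expect_true(all(sc >= 0 & sc <= 100))
  mort <- predictMortality(sig@forest, tab)
  expect_equal(sc[which.min(mort)], 0)
  expect_equal(sc[which.max(mort)], 100)
  dup <- tab[c(5, 5), ]
  expect_equal(signatureScore(sig, dup)[1], signatureScore(sig, dup)[2])

  held <- planted_survival(150, 12, informative = 1:3, beta = 1.2,
                           seed = 56)
  colnames(held$X) <- colnames(d$X)
  sch <- suppressWarnings(signatureScore(sig, held$X))
  expect_gte(cor(sch, held$risk, method = "spearman"), 0.4)
})

test_that("missing model features raise an error naming the column", {
  d <- planted_survival(60, 4, informative = 1, seed = 2)
  m <- fitSurvivalForest(d$X, d$time, d$event, nTrees = 100, seed = 1)
  expect_error(predictMortality(m, d$X[, -1]), "f01")
})
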