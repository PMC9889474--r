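# Feature extraction: discretization, first-order, shape, GLCM, GLRLM.

make_disc <- function(levels, nlev) {
  new("DiscretizedRegion", levels = levels, nLevels = as.integer(nlev),
      edges = seq(0, nlev))
}

test_that("discretization: constant region, exact 32-level spread, and
           histogram conservation", {
  g <- voxelGrid(array(5, c(4, 4, 2)))
  m <- binaryMask(array(TRUE, c(4, 4, 2)))
  d <- discretize(g, m)
  expect_true(all(d@levels[gridValues(m)] == 1L))

  g2 <- voxelGrid(array(0:31, c(4, 4, 2)))
  d2 <- discretize(g2, m, nBins = 32)
  expect_equal(sort(unique(as.vector(d2@levels[gridValues(m)]))), 1:32)
  expect_equal(tabulate(d2@levels[gridValues(m)], 32), rep(1L, 32))

  g3 <- voxelGrid(array(rnorm(32), c(4, 4, 2)))
  d3 <- discretize(g3, m, nBins = 8)
  expect_equal(sum(tabulate(d3@levels[gridValues(m)], 8)), 32)
  expect_error(discretize(g3, binaryMask(array(FALSE, c(4, 4, 2)))),
               "empty")
})

test_that("first-order statistics: constant region, small exact case and
           moment recovery for standard normal draws", {
  m <- binaryMask(array(TRUE, c(4, 4, 4)))
  fo <- firstOrderFeatures(voxelGrid(array(3, c(4, 4, 4))), m)
  expect_equal(unname(fo["variance"]), 0)
  expect_equal(unname(fo["entropy"]), 0)
  expect_equal(unname(fo["uniformity"]), 1)

  g <- voxelGrid(array(rep(1:4, 16), c(4, 4, 4)))
  fo2 <- firstOrderFeatures(g, m)
  expect_equal(unname(fo2["mean"]), 2.5)
  expect_equal(unname(fo2["range"]), 3)
  expect_equal(unname(fo2["median"]), 2.5)

  withr::with_seed(11, {
    big <- voxelGrid(array(rnorm(10000), c(25, 25, 16)))
    mb <- binaryMask(array(TRUE, c(25, 25, 16)))
    fb <- firstOrderFeatures(big, mb)
    expect_lt(abs(fb[["skewness"]]), 0.08)
    expect_lt(abs(fb[["kurtosis"]]), 0.15)
  })
})

test_that("single-voxel region: variance 0, skewness/kurtosis missing", {
  arr <- array(FALSE, c(3, 3, 3)); arr[2, 2, 2] <- TRUE
  fo <- firstOrderFeatures(voxelGrid(array(rnorm(27), c(3, 3, 3))),
                           binaryMask(arr))
  expect_equal(unname(fo["variance"]), 0)
  expect_true(is.na(fo["skewness"]) && is.na(fo["kurtosis"]))
})

test_that("intensity-shift equivariance: mean shifts by c, variance and
           texture are unchanged", {
  withr::with_seed(4, {
    g <- voxelGrid(array(rnorm(8^3), c(8, 8, 8)))
    m <- binaryMask(array(runif(8^3) > 0.3, c(8, 8, 8)))
    gs <- voxelGrid(gridValues(g) + 17.5)
    f1 <- firstOrderFeatures(g, m); f2 <- firstOrderFeatures(gs, m)
    expect_equal(unname(f2["mean"] - f1["mean"]), 17.5)
    expect_equal(unname(f2["min"] - f1["min"]), 17.5)
    expect_equal(f2[["variance"]], f1[["variance"]])
    d1 <- discretize(g, m); d2 <- discretize(gs, m)
    expect_identical(d1@levels, d2@levels)  # range-relative binning
    expect_equal(glcmFeatures(d1), glcmFeatures(d2))
    expect_equal(glrlmFeatures(d1), glrlmFeatures(d2))
  })
})

test_that("shape features: digital sphere sphericity near 1, ellipsoid
           elongation matches the generating axes, diameter oracle", {
  s <- sphere_mask(10, margin = 3)
  fs <- shapeFeatures(s)
  expect_gte(fs[["sphericity"]], 0.95)
  expect_lte(fs[["sphericity"]], 1.02)
  expect_lt(abs(fs[["max_diameter_3d"]] - 20), sqrt(3) + 1e-9)
  expect_lt(abs(fs[["mesh_volume"]] - 4188.79) / 4188.79, 0.08)

  e <- ellipsoid_mask(c(20, 10, 10), margin = 3)
  fe <- shapeFeatures(e)
  expect_lt(abs(fe[["elongation"]] - 0.5) / 0.5, 0.05)
  expect_lt(abs(fe[["flatness"]] - 0.5) / 0.5, 0.05)
  expect_lt(fe[["sphericity"]], fs[["sphericity"]])
})

test_that("degenerate planar mask flags mesh features as missing", {
  arr <- array(FALSE, c(6, 6, 6)); arr[2:5, 2:5, 3] <- TRUE
  fp <- shapeFeatures(binaryMask(arr))
  expect_true(is.na(fp[["mesh_volume"]]))
  expect_true(is.na(fp[["sphericity"]]))
  expect_false(is.na(fp[["voxel_volume"]]))
})

test_that("GLCM: checkerboard oracle is exact and constant regions are
           degenerate", {
  lev <- array(0L, c(4, 4, 3))
  lev[, , 2] <- outer(1:4, 1:4, function(i, j) ((i + j) %% 2) + 1L)
  d <- make_disc(lev, 2)
  g <- glcmFeatures(d, offsets = matrix(c(1L, 0L, 0L), 1))
  expect_equal(unname(g["contrast"]), 1.0)
  expect_equal(unname(g["energy"]), 0.5)
  expect_equal(unname(g["homogeneity"]), 0.5)

  levc <- array(0L, c(4, 4, 3)); levc[, , 2] <- 1L
  gc <- glcmFeatures(make_disc(levc, 2))
  expect_equal(unname(gc["contrast"]), 0)
  expect_equal(unname(gc["energy"]), 1)
  expect_true(is.na(gc["correlation"]))
})

test_that("GLCM features invariant under the symmetric level flip", {
  withr::with_seed(8, {
    n <- 5L
    lev <- array(sample(0:n, 6^3, TRUE), c(6, 6, 6))
    flip <- lev
    flip[lev > 0] <- n + 1L - lev[lev > 0]
    a <- glcmFeatures(make_disc(lev, n))
    b <- glcmFeatures(make_disc(flip, n))
    for (f in c("contrast", "dissimilarity", "energy", "homogeneity",
                "entropy"))
      expect_equal(a[[f]], b[[f]], tolerance = 1e-12)
  })
})

test_that("GLCM and GLRLM match brute-force enumeration on random 6^3
           regions", {
  offs <- DeltaRadiomics:::.OFFSETS_13
  for (s in 1:25) {
    withr::with_seed(s, {
      lev <- array(sample(0:4, 6^3, TRUE), c(6, 6, 6))
      d <- make_disc(lev, 4)
      off <- offs[sample(nrow(offs), 1), ]
      P <- DeltaRadiomics:::.glcm_matrix_cpp(lev, dim(lev), 4L,
                                             as.integer(off))
      expect_equal(P, brute_glcm(lev, 4, off), tolerance = 1e-12,
                   ignore_attr = TRUE)
      R <- DeltaRadiomics:::.glrlm_matrix_cpp(lev, dim(lev), 4L,
                                              as.integer(off))
      Rb <- brute_glrlm(lev, 4, off)
      expect_equal(R[, seq_len(ncol(Rb))], Rb, tolerance = 1e-12,
                   ignore_attr = TRUE)
      # run-length conservation: sum(R * length) = in-mask voxels
      expect_equal(sum(sweep(R, 2, seq_len(ncol(R)), `*`)),
                   sum(lev > 0))
    })
  }
})

test_that("GLRLM: constant cube and checkerboard limits", {
  lev <- array(0L, c(6, 6, 6)); lev[2:5, 2:5, 2:5] <- 1L
  rl <- glrlmFeatures(make_disc(lev, 1),
                      directions = matrix(c(1L, 0L, 0L), 1))
  expect_equal(unname(rl["run_percentage"]), 16 / 64)
  expect_equal(unname(rl["lre"]), 16)

  # along directions of odd component sum every run has length 1
  chk <- array(0L, c(4, 4, 4))
  chk[] <- ((slice.index(chk, 1) + slice.index(chk, 2) +
               slice.index(chk, 3)) %% 2) + 1L
  oddDirs <- matrix(c(1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 1L, 1L, 1L, 1L),
                    ncol = 3, byrow = TRUE)
  rc <- glrlmFeatures(make_disc(chk, 2), directions = oddDirs)
  expect_equal(unname(rc["sre"]), 1)
  expect_equal(unname(rc["run_percentage"]), 1)
})

test_that("full extraction: fixed arity, determinism and translation
           invariance", {
  withr::with_seed(21, {
    m <- sphere_mask(7, margin = 15)
    d <- gridDim(m)
    g <- voxelGrid(array(rnorm(prod(d)), d))
    lung <- binaryMask(array(TRUE, d))
    rs <- suppressMessages(makeRings(m, lung))
    fv <- extractFeatures(g, rs, "F0")
    expect_length(fv, 96)
    expect_false(any(duplicated(names(fv))))
    expect_identical(fv, extractFeatures(g, rs, "F0"))

    # translate grid + masks together by 3 voxels along x
    shift <- function(a, by) {
      out <- array(if (is.logical(a)) FALSE else 0, dim(a))
      out[(1 + by):dim(a)[1], , ] <- a[seq_len(dim(a)[1] - by), , ]
      out
    }
    g2 <- voxelGrid(shift(gridValues(g), 3))
    rs2 <- suppressMessages(makeRings(
      binaryMask(shift(gridValues(m), 3)), lung))
    fv2 <- extractFeatures(g2, rs2, "F0")
    expect_equal(fv, fv2, tolerance = 1e-8)
  })
})
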