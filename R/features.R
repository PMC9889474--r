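# Feature catalogue: 16 first-order + 12 shape (tumor only) + 6 GLCM +
# 6 GLRLM features per region. Texture matrices are direction-averaged over
# the 13 unique 3D unit offsets; discretization is fixed-bin-number,
# range-relative (so texture is invariant to intensity shifts).

# the 13 unique 3D unit offsets (one of each +/- pair)
.OFFSETS_13 <- local({
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  keep <- apply(offs, 1, function(o) {
    o <- as.numeric(o)
    first <- o[which(o != 0)[1]]
    first > 0
  })
  as.matrix(offs[keep, , drop = FALSE])
})

#' Discretized in-region intensities
#'
#' @slot levels integer 3D array; 1..nLevels inside the mask, 0 outside.
#' @slot nLevels number of gray levels.
#' @slot edges bin edges (strictly increasing, length nLevels + 1).
#' @exportClass DiscretizedRegion
setClass("DiscretizedRegion",
  representation(levels = "array", nLevels = "integer", edges = "numeric"))

#' Discretize in-region intensities into equal-width bins
#'
#' Equal-width bins spanning the in-region intensity range (fixed bin
#' number). A constant region maps every voxel to level 1.
#'
#' @param grid a [VoxelGrid-class].
#' @param mask a nonempty [BinaryMask-class] on the same grid.
#' @param nBins number of gray levels (>= 2, default 32).
#' @return a [DiscretizedRegion-class].
#' @export
discretize <- function(grid, mask, nBins = 32) {
  stopifnot(is(grid, "VoxelGrid"), is(mask, "BinaryMask"), nBins >= 2)
  inMask <- mask@values
  if (!any(inMask)) stop("empty mask")
  v <- grid@values[inMask]
  lo <- min(v); hi <- max(v)
  lev <- array(0L, dim = dim(grid@values))
  if (hi - lo < .Machine$double.eps * max(1, abs(hi))) {
    lev[inMask] <- 1L
    edges <- lo + seq(0, 1, length.out = nBins + 1)
  } else {
    w <- (hi - lo) / nBins
    lv <- pmin(as.integer(floor((v - lo) / w)) + 1L, as.integer(nBins))
    lev[inMask] <- lv
    edges <- lo + w * 0:nBins
  }
  new("DiscretizedRegion", levels = lev, nLevels = as.integer(nBins),
      edges = edges)
}

#' First-order intensity statistics of a region
#'
#' Mean, median, variance, skewness, excess kurtosis, energy, RMS, entropy,
#' uniformity, min, max, range, P10, P90, IQR and mean absolute deviation,
#' computed from in-region intensities only. Entropy (natural log) and
#' uniformity are computed on the discretized histogram. A single-voxel
#' region has variance 0 and missing skewness/kurtosis.
#'
#' @param grid a [VoxelGrid-class].
#' @param mask a nonempty [BinaryMask-class].
#' @param nBins gray levels for the entropy/uniformity histogram.
#' @return named numeric vector (family `first_order`).
#' @export
firstOrderFeatures <- function(grid, mask, nBins = 32) {
  stopifnot(is(grid, "VoxelGrid"), is(mask, "BinaryMask"))
  v <- grid@values[mask@values]
  if (length(v) == 0) stop("empty mask")
  n <- length(v)
  m <- mean(v)
  s2 <- mean((v - m)^2)  # population variance
  s <- sqrt(s2)
  skew <- if (n < 3 || s == 0) NA_real_ else mean((v - m)^3) / s^3
  kurt <- if (n < 4 || s == 0) NA_real_ else mean((v - m)^4) / s^4 - 3
  disc <- discretize(grid, mask, nBins = nBins)
  p <- tabulate(disc@levels[mask@values], nbins = disc@nLevels) / n
  p <- p[p > 0]
  c(mean = m,
    median = median(v),
    variance = s2,
    skewness = skew,
    kurtosis = kurt,
    energy = sum(v^2),
    rms = sqrt(mean(v^2)),
    entropy = -sum(p * log(p)),
    uniformity = sum(p^2),
    min = min(v),
    max = max(v),
    range = max(v) - min(v),
    p10 = unname(quantile(v, 0.10, type = 7)),
    p90 = unname(quantile(v, 0.90, type = 7)),
    iqr = unname(quantile(v, 0.75) - quantile(v, 0.25)),
    mad = mean(abs(v - m)))
}

#' Shape features of a mask
#'
#' Voxel-count volume, mesh volume and surface area from a marching-
#' tetrahedra isosurface of the (optionally smoothed) binary mask,
#' surface-to-volume ratio, sphericity, compactness, maximum 3D diameter,
#' and the principal-axis lengths / elongation / flatness from a PCA of the
#' voxel-centre coordinates. Degenerate (planar or < 8 voxel) masks have
#' their mesh features flagged missing.
#'
#' @param mask a nonempty [BinaryMask-class].
#' @param smoothSigma Gaussian pre-smoothing of the binary field before
#'   meshing, in voxels (default 1.0; the mesh is taken at iso 0.5).
#'   Smoothing suppresses the voxelization staircase, whose facets
#'   otherwise inflate the surface area of smooth objects by ~25-30%;
#'   at the default a 10 mm digital sphere measures sphericity ~0.99.
#' @return named numeric vector (family `shape`).
#' @export
shapeFeatures <- function(mask, smoothSigma = 1.0) {
  stopifnot(is(mask, "BinaryMask"))
  vox <- which(mask@values, arr.ind = TRUE)
  if (nrow(vox) == 0) stop("empty mask")
  sp <- mask@spacing
  nvox <- nrow(vox)
  voxelVolume <- nvox * prod(sp) # mm^3

  # PCA on physical coordinates
  coords <- sweep(vox - 1, 2, sp, `*`)
  axes <- c(major_axis = NA_real_, minor_axis = NA_real_,
            least_axis = NA_real_, elongation = NA_real_,
            flatness = NA_real_)
  if (nvox >= 2) {
    ev <- sort(eigen(stats::cov(coords), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
    axes["major_axis"] <- 4 * sqrt(ev[1])
    axes["minor_axis"] <- 4 * sqrt(ev[2])
    axes["least_axis"] <- 4 * sqrt(ev[3])
    if (ev[1] > 0) {
      axes["elongation"] <- sqrt(ev[2] / ev[1])
      axes["flatness"] <- sqrt(ev[3] / ev[1])
    }
  }

  # mesh features on a zero-padded field
  meshArea <- NA_real_; meshVol <- NA_real_
  degenerate <- nvox < 8 ||
    any(apply(vox, 2, function(ix) length(unique(ix))) < 2)
  if (!degenerate) {
    d <- dim(mask@values)
    padded <- array(0, d + 2L)
    padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <-
      as.numeric(mask@values)
    if (smoothSigma > 0)
      padded <- .gaussian_blur_cpp(padded, dim(padded),
                                   rep(smoothSigma, 3))
    av <- .mesh_area_volume_cpp(as.numeric(padded), dim(padded),
                                as.numeric(sp))
    meshArea <- av[1]; meshVol <- av[2]
  }
  sphericity <- if (is.na(meshArea) || meshArea <= 0) NA_real_
                else pi^(1 / 3) * (6 * meshVol)^(2 / 3) / meshArea
  compactness <- if (is.na(meshArea) || meshArea <= 0) NA_real_
                 else 36 * pi * meshVol^2 / meshArea^3

  # maximum 3D diameter over boundary voxels
  bnd <- .boundary_voxels(mask)
  maxDiam <- if (nrow(bnd) >= 2) .max_diameter_cpp(bnd)
             else sqrt(sum(sp^2))

  c(voxel_volume = voxelVolume,
    mesh_volume = meshVol,
    surface_area = meshArea,
    surface_to_volume = if (is.na(meshArea) || meshVol == 0) NA_real_
                        else meshArea / meshVol,
    sphericity = sphericity,
    compactness = compactness,
    max_diameter_3d = maxDiam,
    axes)
}

# boundary voxels (6-connectivity) as physical coordinates
.boundary_voxels <- function(mask) {
  m <- mask@values
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  inner <- core &
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  vox <- which(core & !inner, arr.ind = TRUE)
  sweep(vox - 1, 2, mask@spacing, `*`)
}

#' Gray-level co-occurrence features
#'
#' Co-occurrence is counted at distance 1 over the supplied offsets
#' (default: the 13 unique 3D unit offsets), symmetrized and normalized per
#' offset; only voxel pairs with both ends inside the mask count. Feature
#' values (contrast, dissimilarity, energy = angular second moment,
#' homogeneity/IDM, entropy, correlation) are averaged across offsets.
#' Correlation is missing when fewer than 2 gray levels are occupied.
#'
#' @param disc a [DiscretizedRegion-class].
#' @param offsets integer matrix of offsets (rows = `(dx, dy, dz)`).
#' @return named numeric vector (family `glcm`).
#' @export
glcmFeatures <- function(disc, offsets = .OFFSETS_13) {
  stopifnot(is(disc, "DiscretizedRegion"))
  offsets <- matrix(as.integer(offsets), ncol = 3)
  feats <- apply(offsets, 1, function(off) {
    P <- .glcm_matrix_cpp(disc@levels, as.integer(dim(disc@levels)),
                          disc@nLevels, as.integer(off))
    if (sum(P) == 0) return(rep(NA_real_, 6))
    .glcm_stats(P)
  })
  out <- rowMeans(feats, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  names(out) <- c("contrast", "dissimilarity", "energy", "homogeneity",
                  "entropy", "correlation")
  out
}

# features of one normalized symmetric GLCM
.glcm_stats <- function(P) {
  n <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu <- sum(seq_len(n) * px)
  sig2 <- sum((seq_len(n) - mu)^2 * px)
  corr <- if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else NA_real_
  pnz <- P[P > 0]
  c(contrast = sum(P * (i - j)^2),
    dissimilarity = sum(P * abs(i - j)),
    energy = sum(P^2),
    homogeneity = sum(P / (1 + (i - j)^2)),
    entropy = -sum(pnz * log(pnz)),
    correlation = corr)
}

#' Gray-level run-length features
#'
#' Run-length matrices are built per direction (13 unique 3D directions),
#' with runs confined to in-mask voxels; features (SRE, LRE, GLN, RLN, run
#' percentage, run entropy) are averaged across directions.
#'
#' @param disc a [DiscretizedRegion-class].
#' @param directions integer matrix of directions (rows = `(dx, dy, dz)`).
#' @return named numeric vector (family `glrlm`).
#' @export
glrlmFeatures <- function(disc, directions = .OFFSETS_13) {
  stopifnot(is(disc, "DiscretizedRegion"))
  directions <- matrix(as.integer(directions), ncol = 3)
  np <- sum(disc@levels > 0)
  if (np == 0) stop("empty region")
  feats <- apply(directions, 1, function(dir) {
    R <- .glrlm_matrix_cpp(disc@levels, as.integer(dim(disc@levels)),
                           disc@nLevels, as.integer(dir))
    .glrlm_stats(R, np)
  })
  out <- rowMeans(feats)
  names(out) <- c("sre", "lre", "gln", "rln", "run_percentage",
                  "run_entropy")
  out
}

.glrlm_stats <- function(R, nVoxels) {
  nr <- sum(R)
  jl <- col(R)
  p <- R[R > 0] / nr
  c(sre = sum(R / jl^2) / nr,
    lre = sum(R * jl^2) / nr,
    gln = sum(rowSums(R)^2) / nr,
    rln = sum(colSums(R)^2) / nr,
    run_percentage = nr / nVoxels,
    run_entropy = -sum(p * log(p)))
}

#' Extract the full feature catalogue for one scan
#'
#' Concatenates first-order, GLCM and GLRLM features for each of the three
#' regions (tumor, peri5, peri10) plus shape features for the tumor region
#' only (the rings are derived shells whose geometry is determined by the
#' tumor). Names are structured as
#' `<timepoint>__<region>__<family>__<feature>`. Individual feature
#' failures are recorded as `NA`, not fatal.
#'
#' @param grid the (isotropically resampled) [VoxelGrid-class].
#' @param regions a [RegionSet-class] on the same grid.
#' @param timepointTag name prefix, e.g. `"F0"`, `"F1"`.
#' @param nBins gray levels for discretization.
#' @return named numeric vector of `3 * 28 + 12 = 96` features.
#' @export
extractFeatures <- function(grid, regions, timepointTag = "F0",
                            nBins = 32) {
  stopifnot(is(grid, "VoxelGrid"), is(regions, "RegionSet"))
  out <- numeric(0)
  for (rn in c("tumor", "peri5", "peri10")) {
    mask <- slot(regions, rn)
    fo <- tryCatch(firstOrderFeatures(grid, mask, nBins = nBins),
                   error = function(e) setNames(rep(NA_real_, 16),
                     names(firstOrderFeatures(
                       voxelGrid(array(1:8, c(2, 2, 2))),
                       binaryMask(array(TRUE, c(2, 2, 2)))))))
    disc <- tryCatch(discretize(grid, mask, nBins = nBins),
                     error = function(e) NULL)
    gl <- if (is.null(disc)) setNames(rep(NA_real_, 6),
            c("contrast", "dissimilarity", "energy", "homogeneity",
              "entropy", "correlation"))
          else glcmFeatures(disc)
    rl <- if (is.null(disc)) setNames(rep(NA_real_, 6),
            c("sre", "lre", "gln", "rln", "run_percentage", "run_entropy"))
          else glrlmFeatures(disc)
    names(fo) <- paste(timepointTag, rn, "first_order", names(fo),
                       sep = "__")
    names(gl) <- paste(timepointTag, rn, "glcm", names(gl), sep = "__")
    names(rl) <- paste(timepointTag, rn, "glrlm", names(rl), sep = "__")
    out <- c(out, fo, gl, rl)
  }
  sh <- tryCatch(shapeFeatures(regions@tumor),
                 error = function(e) setNames(rep(NA_real_, 12),
                   c("voxel_volume", "mesh_volume", "surface_area",
                     "surface_to_volume", "sphericity", "compactness",
                     "max_diameter_3d", "major_axis", "minor_axis",
                     "least_axis", "elongation", "flatness")))
  names(sh) <- paste(timepointTag, "tumor", "shape", names(sh), sep = "__")
  c(out, sh)
}
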