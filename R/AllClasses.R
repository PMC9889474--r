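#' @title Core image containers
#'
#' @description `VoxelGrid` holds a 3D scalar image on a physical grid:
#' voxel-center convention, 0-based indices, world = origin + index *
#' spacing, axis order (x, y, z). `BinaryMask` is a `VoxelGrid` whose values
#' are logical. All spacings and origins are in millimetres.
#'
#' @slot values 3D array of voxel values.
#' @slot spacing numeric(3), voxel spacing in mm (> 0).
#' @slot origin numeric(3), world coordinate of voxel (0, 0, 0) in mm.
#'
#' @name VoxelGrid-class
#' @aliases VoxelGrid-class BinaryMask-class
#' @exportClass VoxelGrid
setClass("VoxelGrid",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  prototype(values = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0)))

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite numbers (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite numbers (mm)")
  if (length(msg)) msg else TRUE
})

#' @exportClass BinaryMask
setClass("BinaryMask", contains = "VoxelGrid")

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@values))
    return("mask values must be logical")
  TRUE
})

#' Intratumoral and peritumoral regions of one scan
#'
#' Tumor mask plus the two clipped peritumoral rings. The three masks are
#' pairwise disjoint by construction: `peri5` is the 5 mm dilation minus the
#' tumor and `peri10` the 10 mm dilation minus the 5 mm dilation, both
#' intersected with the lung mask.
#'
#' @slot tumor,peri5,peri10 [BinaryMask-class] objects on a common grid.
#' @exportClass RegionSet
setClass("RegionSet",
  representation(tumor = "BinaryMask", peri5 = "BinaryMask",
                 peri10 = "BinaryMask"))

setValidity("RegionSet", function(object) {
  msg <- character()
  dt <- dim(object@tumor@values)
  if (!identical(dt, dim(object@peri5@values)) ||
      !identical(dt, dim(object@peri10@values)))
    msg <- c(msg, "region masks must share one grid")
  if (any(object@tumor@values & object@peri5@values) ||
      any(object@tumor@values & object@peri10@values) ||
      any(object@peri5@values & object@peri10@values))
    msg <- c(msg, "tumor/peri5/peri10 must be pairwise disjoint")
  if (length(msg)) msg else TRUE
})

#' One patient's baseline / follow-up scan pair
#'
#' Baseline (F0) and first follow-up (F1) images with their tumor masks, the
#' lung mask used for ring clipping, and the inter-scan interval in days.
#'
#' @slot f0,f1 [VoxelGrid-class] images.
#' @slot f0Mask,f1Mask,lungMask [BinaryMask-class] segmentations.
#' @slot intervalDays numeric(1), days between the two scans (>= 1).
#' @exportClass ScanPair
setClass("ScanPair",
  representation(f0 = "VoxelGrid", f0Mask = "BinaryMask",
                 f1 = "VoxelGrid", f1Mask = "BinaryMask",
                 lungMask = "BinaryMask", intervalDays = "numeric"))

setValidity("ScanPair", function(object) {
  msg <- character()
  if (length(object@intervalDays) != 1L || !is.finite(object@intervalDays) ||
      object@intervalDays < 1)
    msg <- c(msg, "intervalDays must be a single number >= 1")
  if (!any(object@f0Mask@values) || !any(object@f1Mask@values))
    msg <- c(msg, "tumor masks must be nonempty")
  if (length(msg)) msg else TRUE
})

#' Assembled modeling table with persisted preprocessing parameters
#'
#' Produced by [assembleFeatureTable()]. Holds the patients-by-features
#' modeling table (retained F0 + retained F1 + per-day delta columns) along
#' with the training-cohort imputation medians and the per-feature epsilon
#' guards, so a validation cohort can be transformed without leakage.
#'
#' @slot table data.frame, rows = patients (`patient_id` column first).
#' @slot medians named numeric, training-cohort imputation medians.
#' @slot epsilon named numeric, per-feature near-zero guard for deltas.
#' @slot dropped character, delta columns dropped for excess missingness.
#' @exportClass AssembledFeatures
setClass("AssembledFeatures",
  representation(table = "data.frame", medians = "numeric",
                 epsilon = "numeric", dropped = "character"))

#' Fitted random survival forest wrapper
#'
#' Wraps a ranger survival forest (log-rank splits) together with the
#' feature names it was trained on, its out-of-bag ensemble mortality for
#' the training patients and the fitting parameters.
#'
#' @slot fit the underlying ranger object.
#' @slot featureNames character, training feature columns (order fixed).
#' @slot oobMortality numeric, OOB ensemble mortality per training patient.
#' @slot oobCIndex numeric(1), OOB Harrell C of the forest.
#' @slot params list of hyperparameters (num.trees, mtry, min.node.size,
#'   seed).
#' @exportClass RSFModel
setClass("RSFModel",
  representation(fit = "ANY", featureNames = "character",
                 oobMortality = "numeric", oobCIndex = "numeric",
                 params = "list"))

#' Boruta selection result
#'
#' Confirmed / rejected / tentative feature sets with the per-iteration
#' importance history and a final importance ranking.
#'
#' @slot confirmed,rejected,tentative character vectors (disjoint; union =
#'   candidate set).
#' @slot importanceHistory matrix, iterations x candidates (NA once a
#'   feature has been rejected and removed).
#' @slot shadowMaxHistory numeric, max shadow importance per iteration.
#' @slot ranking named numeric, median importance per feature (descending).
#' @slot nIter integer, iterations run.
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(confirmed = "character", rejected = "character",
                 tentative = "character", importanceHistory = "matrix",
                 shadowMaxHistory = "numeric", ranking = "numeric",
                 nIter = "integer"))

#' Radiomics signature model
#'
#' A pool-restricted Boruta selection refit as a random survival forest on
#' the top-k features, with the training min--max scaling that maps ensemble
#' mortality to a 0--100 signature score.
#'
#' @slot pool one of "all", "baseline", "intratumor".
#' @slot features character, the selected feature names (<= k).
#' @slot forest [RSFModel-class].
#' @slot scoreRange numeric(2), training mortality range used for scaling.
#' @slot selection [SelectionResult-class] from the pool run.
#' @exportClass SignatureModel
setClass("SignatureModel",
  representation(pool = "character", features = "character",
                 forest = "RSFModel", scoreRange = "numeric",
                 selection = "SelectionResult"))

#' Risk stratification result
#'
#' Maximally selected log-rank cutoff with the candidate profile, the
#' rapid/slow group labels, per-group median PFS and the log-rank test on
#' the induced split.
#'
#' @slot cutoff numeric(1), signature-score cutoff.
#' @slot groups factor, "rapid" (score > cutoff) / "slow" per patient.
#' @slot profile data.frame with columns `cutoff` and `statistic`.
#' @slot medianPFS named numeric, per-group median PFS in months (NA when
#'   the curve never reaches 0.5).
#' @slot logrank named numeric: `statistic`, `p`, and `p_permutation` when
#'   computed (the plain p is anti-conservative after a maximized split).
#' @exportClass StratificationResult
setClass("StratificationResult",
  representation(cutoff = "numeric", groups = "factor",
                 profile = "data.frame", medianPFS = "numeric",
                 logrank = "numeric"))
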