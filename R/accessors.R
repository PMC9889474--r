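#' Constructors and accessors for image containers
#'
#' @param values 3D numeric or logical array.
#' @param spacing numeric(3), voxel spacing in mm.
#' @param origin numeric(3), world position of voxel (0,0,0) in mm.
#' @return `voxelGrid()` a [VoxelGrid-class]; `binaryMask()` a
#'   [BinaryMask-class].
#' @examples
#' g <- voxelGrid(array(rnorm(27), c(3, 3, 3)))
#' gridDim(g)
#' @export
voxelGrid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("VoxelGrid", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @rdname voxelGrid
#' @export
binaryMask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(values) <- "logical"
  new("BinaryMask", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @rdname voxelGrid
#' @param x a [VoxelGrid-class] or [BinaryMask-class].
#' @export
gridValues <- function(x) x@values

#' @rdname voxelGrid
#' @export
gridSpacing <- function(x) x@spacing

#' @rdname voxelGrid
#' @export
gridOrigin <- function(x) x@origin

#' @rdname voxelGrid
#' @export
gridDim <- function(x) dim(x@values)

#' @rdname voxelGrid
#' @export
voxelVolumeMm3 <- function(x) prod(x@spacing)

#' Region accessors
#' @param x a [RegionSet-class].
#' @return the requested [BinaryMask-class].
#' @export
tumorMask <- function(x) x@tumor

#' @rdname tumorMask
#' @export
peri5Mask <- function(x) x@peri5

#' @rdname tumorMask
#' @export
peri10Mask <- function(x) x@peri10

#' Scan pair accessors
#' @param x a [ScanPair-class].
#' @return the requested component.
#' @export
intervalDays <- function(x) x@intervalDays

#' @rdname intervalDays
#' @param timepoint `"F0"` or `"F1"`.
#' @export
scanGrid <- function(x, timepoint = c("F0", "F1")) {
  timepoint <- match.arg(timepoint)
  if (timepoint == "F0") x@f0 else x@f1
}

#' @rdname intervalDays
#' @export
scanMask <- function(x, timepoint = c("F0", "F1")) {
  timepoint <- match.arg(timepoint)
  if (timepoint == "F0") x@f0Mask else x@f1Mask
}

#' @rdname intervalDays
#' @export
lungMask <- function(x) x@lungMask

setMethod("show", "VoxelGrid", function(object) {
  cat(class(object), ": ", paste(dim(object@values), collapse = " x "),
      " voxels, spacing ", paste(signif(object@spacing, 3), collapse = "/"),
      " mm\n", sep = "")
  if (is(object, "BinaryMask"))
    cat("  foreground voxels: ", sum(object@values), "\n", sep = "")
})

setMethod("show", "RegionSet", function(object) {
  cat("RegionSet: tumor ", sum(object@tumor@values), " | peri5 ",
      sum(object@peri5@values), " | peri10 ", sum(object@peri10@values),
      " voxels\n", sep = "")
})

setMethod("show", "ScanPair", function(object) {
  cat("ScanPair: interval ", object@intervalDays, " days; F0 tumor ",
      sum(object@f0Mask@values), " vox, F1 tumor ",
      sum(object@f1Mask@values), " vox\n", sep = "")
})

setMethod("show", "SignatureModel", function(object) {
  cat("SignatureModel [", object@pool, "]: ", length(object@features),
      " features, OOB C-index ", round(object@forest@oobCIndex, 3), "\n",
      sep = "")
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult: ", length(object@confirmed), " confirmed, ",
      length(object@rejected), " rejected, ", length(object@tentative),
      " tentative after ", object@nIter, " iterations\n", sep = "")
})

setMethod("show", "StratificationResult", function(object) {
  cat("StratificationResult: cutoff ", signif(object@cutoff, 4),
      "; rapid n=", sum(object@groups == "rapid"), ", slow n=",
      sum(object@groups == "slow"), "; log-rank p=",
      signif(object@logrank[["p"]], 3), "\n", sep = "")
})
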