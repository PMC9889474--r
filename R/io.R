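#' Read and write 3D volumes as NIfTI-1
#'
#' Thin wrappers around RNifti preserving voxel values, spacing and origin.
#' Only 3D images are accepted; masks are read back as [BinaryMask-class]
#' when `mask = TRUE` (values re-binarized at 0.5).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param mask logical; read as a binary mask?
#' @return [readVolume()] a [VoxelGrid-class] (or [BinaryMask-class]);
#'   [writeVolume()] the path, invisibly.
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' g <- voxelGrid(array(rnorm(4^3), c(4, 4, 4)), spacing = c(1, 1, 2.5))
#' writeVolume(g, f)
#' g2 <- readVolume(f)
#' stopifnot(all.equal(gridValues(g), gridValues(g2)))
#' @export
readVolume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), "D: ", path)
  spacing <- RNifti::pixdim(img)
  org <- as.numeric(RNifti::voxelToWorld(c(1, 1, 1), img))
  vals <- array(as.vector(img), dim = d)
  if (mask) binaryMask(vals > 0.5, spacing = spacing, origin = org)
  else voxelGrid(vals, spacing = spacing, origin = org)
}

#' @rdname readVolume
#' @param grid a [VoxelGrid-class] or [BinaryMask-class].
#' @export
writeVolume <- function(grid, path) {
  stopifnot(is(grid, "VoxelGrid"))
  vals <- grid@values
  if (is.logical(vals)) {
    vals <- array(as.integer(vals), dim = dim(vals))
  }
  img <- RNifti::asNifti(vals)
  # sform: diagonal spacing with translation = origin (RAS-ish, axis-aligned)
  xform <- diag(c(grid@spacing, 1))
  xform[1:3, 4] <- grid@origin
  img <- RNifti::`sform<-`(img, structure(xform, code = 2L))
  RNifti::pixdim(img) <- grid@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
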