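#' @include AllClasses.R
NULL

#' Read a 3D volume from NIfTI-1 or Analyze-7.5
#'
#' Reads a `.nii`, `.nii.gz`, `.hdr` or `.img` file (an Analyze pair may
#' be named by either member) and returns a [VoxelVolume-class] holding
#' the voxel array in the file's native axis order and the voxel spacing
#' from the header. Any header scale slope/intercept is applied by the
#' reader before values are returned.
#'
#' Volumes must be explicitly 3D. A trailing 4th dimension of length 1
#' (common with writers that emit nominally-4D headers) is squeezed with
#' a warning; more than 3 non-singleton dimensions are rejected. Array
#' axes are taken as the stored x/y/z directions: no reorientation from
#' the header affine is attempted, and a warning is issued when the
#' header carries a non-identity rotation.
#'
#' @param path path to an existing image file.
#' @return a [VoxelVolume-class].
#' @examples
#' m <- bernoulliField(c(8, 8, 8), p = 0.3, seed = 1, spacing = c(1.5, 1.5, 1.5))
#' f <- file.path(tempdir(), "demo.nii")
#' writeMask(m, f)
#' v <- loadVolume(f)
#' volumeShape(v)
#' @seealso [binarize()], [writeMask()]
#' @export
loadVolume <- function(path) {
  if (length(path) != 1L || !is.character(path))
    stop("'path' must be a single file path")
  if (!file.exists(path))
    stop("input file not found: ", path)
  img <- RNifti::readNifti(path, internal = FALSE)
  d <- dim(img)
  if (is.null(d) || length(d) < 3L)
    stop("volume in ", path, " is not 3D (", length(d),
         " dimensions); make sure input files are explicitly 3D")
  if (length(d) > 3L) {
    extra <- d[-(1:3)]
    if (any(extra > 1L))
      stop("volume in ", path, " is not 3D (dimensions ",
           paste(d, collapse = " x "),
           "); make sure input files are explicitly 3D")
    warning("squeezing trailing singleton dimension(s) of ", path,
            " (header declares ", length(d), "D)")
    img2 <- array(as.numeric(img), dim = d[1:3])
  } else {
    img2 <- array(as.numeric(img), dim = d)
  }
  spacing <- as.numeric(RNifti::pixdim(img))[1:3]
  .warnNonIdentityRotation(img, path)
  new("VoxelVolume", data = img2, spacing = spacing,
      sourceName = basename(path))
}

# warn when the stored xform rotates axes away from the grid; the
# variogram directions always follow the stored array axes
.warnNonIdentityRotation <- function(img, path) {
  rot <- tryCatch({
    xf <- RNifti::xform(img)
    r <- xf[1:3, 1:3, drop = FALSE]
    sweep(r, 2, pmax(sqrt(colSums(r^2)), .Machine$double.eps), "/")
  }, error = function(e) NULL)
  if (is.null(rot)) return(invisible(NULL))
  offdiag <- abs(rot - diag(abs(diag(rot))))
  if (any(offdiag > 1e-3))
    warning("header of ", basename(path), " carries a non-identity ",
            "rotation; axes are used as stored, without reorientation")
  invisible(NULL)
}

#' Binarize a volume into a lesion mask
#'
#' Converts a scalar volume (typically a lesion probability map with
#' values in \[0, 1\]) into a [BinaryMask-class]: voxels strictly greater
#' than `threshold` become 1 (lesion), all others 0. An already binary
#' volume passes through unchanged in content at the default threshold.
#'
#' @param vol a [VoxelVolume-class] (or a [BinaryMask-class], which is
#'   first viewed as a plain volume).
#' @param threshold scalar in \[0, 1\]; default 0.5.
#' @return a [BinaryMask-class].
#' @examples
#' v <- new("VoxelVolume", data = array(c(0, 0.4, 0.5, 0.6, 1, 0, 0, 1),
#'          dim = c(2, 2, 2)), spacing = c(1, 1, 1), sourceName = "demo")
#' lesionCount(binarize(v, 0.5))
#' @export
binarize <- function(vol, threshold = 0.5) {
  stopifnot(is(vol, "VoxelVolume"))
  if (length(threshold) != 1L || !is.finite(threshold) ||
      threshold < 0 || threshold > 1)
    stop("'threshold' must be a single value in [0, 1]")
  nNA <- sum(is.na(vol@data))
  if (nNA > 0)
    stop("volume contains ", nNA, " NaN/NA voxel(s); cannot binarize")
  b <- array(as.numeric(vol@data > threshold), dim = dim(vol@data))
  new("BinaryMask", data = b, spacing = vol@spacing,
      sourceName = vol@sourceName,
      lesionVoxelCount = as.integer(sum(b)),
      thresholdUsed = threshold)
}

#' Write a mask or volume as NIfTI-1
#'
#' Serializes a [VoxelVolume-class] (including [BinaryMask-class]) to a
#' NIfTI-1 file, preserving data, shape and voxel spacing. Mainly used to
#' materialize synthetic test scenes for end-to-end runs.
#'
#' @param vol a [VoxelVolume-class].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return the path, invisibly.
#' @export
writeMask <- function(vol, path) {
  stopifnot(is(vol, "VoxelVolume"))
  img <- RNifti::asNifti(vol@data)
  RNifti::pixdim(img) <- vol@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
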