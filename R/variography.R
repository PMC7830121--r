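#' @include AllClasses.R
NULL

.AXIS_INDEX <- c(x = 1L, y = 2L, z = 3L)

#' Default number of lags for a given voxel spacing
#'
#' The most informative spatial correlation of white-matter lesion masks
#' lives within roughly 0-15 mm, so by default the lag grid is confined
#' to that distance: the number of one-voxel lags is floor(15 mm /
#' coarsest axis spacing), e.g. 10 for 1.5 mm voxels and 15 for 1 mm
#' voxels (at least 3, so a model can still be fitted on very coarse
#' grids).
#'
#' @param spacing numeric(3), voxel size in mm.
#' @param maxDistance maximum lag distance in mm (default 15).
#' @return integer number of lags.
#' @export
autoMaxLag <- function(spacing, maxDistance = 15) {
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  max(3L, as.integer(floor(maxDistance / max(spacing))))
}

.checkLagSpec <- function(maxLag, shape, direction) {
  if (length(maxLag) != 1L || !is.finite(maxLag) || maxLag < 1 ||
      maxLag != round(maxLag))
    stop("'maxLag' must be a positive integer")
  n <- shape[.AXIS_INDEX[[direction]]]
  if (maxLag >= n)
    stop(sprintf(
      "maxLag (%d) must be smaller than the voxel count along %s (%d)",
      as.integer(maxLag), direction, n))
  invisible(as.integer(maxLag))
}

#' Directional empirical variogram of a binary mask
#'
#' Computes the empirical variogram along one grid axis: for each lag
#' k = 1..maxLag,
#' \deqn{\gamma(k) = \frac{1}{2\,n(k)} \sum (z(x_i) - z(x_i + k))^2,}
#' the sum running over all axis-aligned voxel pairs separated by exactly
#' k voxels along `direction`. Every voxel of the array participates
#' (lesion and background alike); pairs that would leave the array are
#' not formed (no wrap-around or padding), so the pair count at lag k
#' along an axis of n voxels is (n - k) times the product of the other
#' two axis lengths. Lags are converted to mm with the spacing of the lag
#' axis.
#'
#' The implementation uses shifted-array differences (one vectorized pass
#' per lag), which is exact on the regular grid: directional pairs are
#' pure shifts, no angular tolerance is involved.
#'
#' @param mask a [BinaryMask-class].
#' @param direction `"x"`, `"y"` or `"z"` (array axes 1, 2, 3).
#' @param maxLag number of one-voxel-wide distance classes; must be
#'   smaller than the axis voxel count. `NULL` selects [autoMaxLag()].
#' @return an [EmpiricalVariogram-class].
#' @examples
#' m <- bernoulliField(c(16, 16, 16), p = 0.5, seed = 7)
#' empiricalVariogram(m, "x", maxLag = 5)
#' @seealso [variogramsXYZ()], [bruteForceVariogram()]
#' @export
empiricalVariogram <- function(mask, direction = c("x", "y", "z"),
                               maxLag = NULL) {
  stopifnot(is(mask, "BinaryMask"))
  direction <- match.arg(direction)
  if (!all(mask@data == 0 | mask@data == 1))
    stop("mask contains non-binary values")
  shape <- dim(mask@data)
  if (is.null(maxLag)) maxLag <- autoMaxLag(mask@spacing)
  maxLag <- .checkLagSpec(maxLag, shape, direction)

  ax <- .AXIS_INDEX[[direction]]
  n <- shape[ax]
  nOther <- prod(shape[-ax])
  x <- mask@data
  gamma <- numeric(maxLag)
  pairs <- numeric(maxLag)
  for (k in seq_len(maxLag)) {
    lo <- seq_len(n - k)
    hi <- lo + k
    dd <- switch(direction,
      x = x[hi, , , drop = FALSE] - x[lo, , , drop = FALSE],
      y = x[, hi, , drop = FALSE] - x[, lo, , drop = FALSE],
      z = x[, , hi, drop = FALSE] - x[, , lo, drop = FALSE])
    pairs[k] <- (n - k) * nOther
    gamma[k] <- sum(dd * dd) / (2 * pairs[k])
  }
  new("EmpiricalVariogram",
      direction = direction,
      lags = seq_len(maxLag),
      distances = seq_len(maxLag) * mask@spacing[ax],
      gamma = gamma,
      pairCounts = pairs)
}

#' Empirical variograms along all three axes
#'
#' Applies [empiricalVariogram()] per axis. Distances are computed with
#' the spacing of each axis, so anisotropic voxels yield different
#' distance grids per direction.
#'
#' @inheritParams empiricalVariogram
#' @return named list of three [EmpiricalVariogram-class] objects
#'   (`x`, `y`, `z`).
#' @examples
#' m <- bernoulliField(c(16, 16, 16), p = 0.3, seed = 11)
#' sapply(variogramsXYZ(m, maxLag = 4), semivariance)
#' @export
variogramsXYZ <- function(mask, maxLag = NULL) {
  stopifnot(is(mask, "BinaryMask"))
  if (is.null(maxLag)) maxLag <- autoMaxLag(mask@spacing)
  out <- lapply(c(x = "x", y = "y", z = "z"), function(d)
    empiricalVariogram(mask, d, maxLag))
  out
}
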