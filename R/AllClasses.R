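#' @import methods
NULL

#' VoxelVolume: a 3D scalar image with voxel geometry
#'
#' Container for a raw 3D voxel array together with its per-axis voxel
#' spacing in millimetres and the name of the originating file. Array axes
#' 1, 2, 3 are taken as the x, y, z directions of the (Montreal Normal
#' Brain) volume as stored on disk; no reorientation is applied.
#'
#' @slot data 3D numeric array, one value per voxel.
#' @slot spacing numeric(3), millimetres per voxel along x, y, z;
#'   strictly positive and finite.
#' @slot sourceName character(1), originating file name (or a synthetic
#'   label for generated volumes).
#'
#' @seealso [loadVolume()], [binarize()], [BinaryMask-class]
#' @export
setClass("VoxelVolume",
  representation(
    data = "array",
    spacing = "numeric",
    sourceName = "character"
  )
)

setValidity("VoxelVolume", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, sprintf("data must be a 3D array, got %d dimensions",
                          length(d)))
  else if (any(d < 2L))
    msg <- c(msg, "each axis needs at least 2 voxels (one pair per axis)")
  if (length(object@spacing) != 3L)
    msg <- c(msg, "spacing must have length 3")
  else if (any(!is.finite(object@spacing)) || any(object@spacing <= 0))
    msg <- c(msg, "spacing entries must be strictly positive and finite")
  if (length(object@sourceName) != 1L)
    msg <- c(msg, "sourceName must be a single string")
  if (length(msg)) msg else TRUE
})

#' BinaryMask: a thresholded \{0, 1\} lesion mask
#'
#' A [VoxelVolume-class] whose voxels are exactly 0 (background) or 1
#' (lesion). This is the substrate of all variography: every voxel of the
#' array, lesion and background alike, participates in pair counting.
#'
#' @slot lesionVoxelCount integer(1), number of 1-voxels.
#' @slot thresholdUsed numeric(1), the binarization threshold applied, or
#'   `NA_real_` when the input was already binary and no threshold was
#'   applied.
#'
#' @seealso [binarize()], [empiricalVariogram()]
#' @export
setClass("BinaryMask",
  contains = "VoxelVolume",
  representation(
    lesionVoxelCount = "integer",
    thresholdUsed = "numeric"
  )
)

setValidity("BinaryMask", function(object) {
  msg <- character()
  v <- object@data
  if (!all(v == 0 | v == 1))
    msg <- c(msg, "mask voxels must all be exactly 0 or 1")
  n1 <- sum(v == 1)
  if (length(object@lesionVoxelCount) != 1L ||
      object@lesionVoxelCount != n1)
    msg <- c(msg, sprintf(
      "lesionVoxelCount (%s) does not match the number of 1-voxels (%d)",
      paste(object@lesionVoxelCount, collapse = ","), n1))
  if (length(object@thresholdUsed) != 1L)
    msg <- c(msg, "thresholdUsed must be a single number (NA = none)")
  if (length(msg)) msg else TRUE
})

#' EmpiricalVariogram: directional semivariance sequence
#'
#' The empirical variogram of a binary mask along one grid axis:
#' gamma(h) = 1 / (2 n(h)) * sum over the n(h) voxel pairs separated by
#' exactly h of the squared value difference. Lags are integer voxel steps
#' 1..max_lag; physical distances use the voxel spacing of the lag axis.
#' For binary data gamma is dimensionless and bounded by 0.5.
#'
#' @slot direction character(1), one of `"x"`, `"y"`, `"z"`.
#' @slot lags integer vector, 1..max_lag voxel steps.
#' @slot distances numeric vector, lag times axis spacing, mm, strictly
#'   increasing.
#' @slot gamma numeric vector, semivariance per lag.
#' @slot pairCounts numeric vector, number of voxel pairs n(h) per lag.
#'
#' @seealso [empiricalVariogram()], [fitExponential()]
#' @export
setClass("EmpiricalVariogram",
  representation(
    direction = "character",
    lags = "integer",
    distances = "numeric",
    gamma = "numeric",
    pairCounts = "numeric"
  )
)

setValidity("EmpiricalVariogram", function(object) {
  msg <- character()
  if (!(length(object@direction) == 1L &&
        object@direction %in% c("x", "y", "z")))
    msg <- c(msg, "direction must be one of 'x', 'y', 'z'")
  k <- length(object@lags)
  if (length(object@distances) != k || length(object@gamma) != k ||
      length(object@pairCounts) != k)
    msg <- c(msg, "lags, distances, gamma and pairCounts must align")
  if (k) {
    if (any(object@gamma < 0))
      msg <- c(msg, "gamma must be non-negative")
    if (any(diff(object@distances) <= 0))
      msg <- c(msg, "distances must be strictly increasing")
    if (any(object@pairCounts < 1))
      msg <- c(msg, "each lag must have at least one pair")
  }
  if (length(msg)) msg else TRUE
})

#' ExpModelFit: fitted exponential variogram model for one direction
#'
#' Parameters of the exponential variogram model
#' gamma(h) = c * (1 - exp(-3 h / a)) fitted by unweighted nonlinear least
#' squares to one directional empirical variogram. `a` (the range, mm) is
#' the distance at which the model reaches ~95% of its sill; `c` (the
#' sill) is the plateau semivariance.
#'
#' @slot direction character(1), `"x"`, `"y"` or `"z"`.
#' @slot a numeric(1), range in mm (> 0 when converged, `NA` otherwise).
#' @slot c numeric(1), sill (> 0 when converged, `NA` otherwise).
#' @slot rss numeric(1), residual sum of squares of the fit.
#' @slot converged logical(1), whether the fit converged to admissible
#'   (strictly positive) parameters.
#' @slot nPoints integer(1), number of lags used.
#' @slot message character(1), diagnostic for non-converged fits.
#'
#' @seealso [fitExponential()], [ldpSummary()]
#' @export
setClass("ExpModelFit",
  representation(
    direction = "character",
    a = "numeric",
    c = "numeric",
    rss = "numeric",
    converged = "logical",
    nPoints = "integer",
    message = "character"
  )
)

setValidity("ExpModelFit", function(object) {
  msg <- character()
  if (!(length(object@direction) == 1L &&
        object@direction %in% c("x", "y", "z")))
    msg <- c(msg, "direction must be one of 'x', 'y', 'z'")
  if (isTRUE(object@converged)) {
    if (!(is.finite(object@a) && object@a > 0))
      msg <- c(msg, "converged fit requires range a > 0")
    if (!(is.finite(object@c) && object@c > 0))
      msg <- c(msg, "converged fit requires sill c > 0")
    if (!(is.finite(object@rss) && object@rss >= 0))
      msg <- c(msg, "rss must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' LDPRecord: one lesion pattern summarized on the log scale
#'
#' One row of the `.var` parameter table: the natural logarithms of the
#' arithmetic means of the per-direction ranges and sills (log of mean,
#' not mean of logs), the per-direction log components, the 1-based input
#' index and the source file name.
#'
#' @slot id integer(1), 1-based index of the input file in the batch.
#' @slot lnMeanA numeric(1), ln(mean(aX, aY, aZ)).
#' @slot lnMeanC numeric(1), ln(mean(cX, cY, cZ)).
#' @slot lnA numeric(3), named c(x=, y=, z=): ln of each directional range.
#' @slot lnC numeric(3), named c(x=, y=, z=): ln of each directional sill.
#' @slot filename character(1), source file name.
#'
#' @seealso [ldpSummary()], [appendVarRecord()], [readVarFile()]
#' @export
setClass("LDPRecord",
  representation(
    id = "integer",
    lnMeanA = "numeric",
    lnMeanC = "numeric",
    lnA = "numeric",
    lnC = "numeric",
    filename = "character"
  )
)

setValidity("LDPRecord", function(object) {
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id) || object@id < 1L)
    msg <- c(msg, "id must be a positive integer")
  if (length(object@lnA) != 3L || length(object@lnC) != 3L ||
      !identical(names(object@lnA), c("x", "y", "z")) ||
      !identical(names(object@lnC), c("x", "y", "z")))
    msg <- c(msg, "lnA and lnC must be length-3 vectors named x, y, z")
  else {
    # mean of positives lies within their range
    if (is.finite(object@lnMeanA) &&
        (object@lnMeanA < min(object@lnA) - 1e-9 ||
         object@lnMeanA > max(object@lnA) + 1e-9))
      msg <- c(msg, "lnMeanA must lie within the per-direction ln(a) range")
    if (abs(exp(object@lnMeanA) - mean(exp(object@lnA))) >
        1e-8 * max(1, exp(object@lnMeanA)))
      msg <- c(msg, "lnMeanA must be the log of the arithmetic mean of a")
  }
  if (length(object@filename) != 1L)
    msg <- c(msg, "filename must be a single string")
  if (length(msg)) msg else TRUE
})

#' RunConfig: batch pipeline configuration
#'
#' Settings for [runPipeline()]. Use the [ldpConfig()] constructor rather
#' than `new()`.
#'
#' @slot inputPaths character, ordered list of input volumes (.nii,
#'   .nii.gz, .hdr, .img).
#' @slot varPath character(1), output `.var` parameter table.
#' @slot ldpPath character(1), output PNG of the discrimination plot.
#' @slot componentLdpPath character(1), output PNG of the per-direction
#'   component plot.
#' @slot imageThreshold numeric(1) in \[0, 1\], binarization threshold.
#' @slot maxLag numeric(1), number of one-voxel lags, or `NA` for
#'   automatic choice (largest lag distance <= 15 mm on the coarsest axis).
#' @slot guessA numeric(1), starting estimate for the range, mm, or `NA`
#'   for automatic (half the maximum lag distance).
#' @slot guessC numeric(1), starting estimate for the sill, or `NA` for
#'   automatic (mean of the upper half of the semivariances).
#' @slot plotWidth,plotHeight numeric(1), PNG pixel dimensions.
#' @slot varioPostfix character(1), postfix appended to each input file
#'   name to name its variogram plot.
#' @slot varioDir character(1), directory for per-file variogram plots;
#'   `NA` means the directory of `varPath`.
#'
#' @export
setClass("RunConfig",
  representation(
    inputPaths = "character",
    varPath = "character",
    ldpPath = "character",
    componentLdpPath = "character",
    imageThreshold = "numeric",
    maxLag = "numeric",
    guessA = "numeric",
    guessC = "numeric",
    plotWidth = "numeric",
    plotHeight = "numeric",
    varioPostfix = "character",
    varioDir = "character"
  )
)

setValidity("RunConfig", function(object) {
  msg <- character()
  if (!length(object@inputPaths))
    msg <- c(msg, "inputPaths must be non-empty")
  outs <- c(object@varPath, object@ldpPath, object@componentLdpPath)
  if (length(outs) != 3L || anyDuplicated(outs))
    msg <- c(msg, "varPath, ldpPath and componentLdpPath must be distinct")
  th <- object@imageThreshold
  if (!(length(th) == 1L && is.finite(th) && th >= 0 && th <= 1))
    msg <- c(msg, "imageThreshold must be a single value in [0, 1]")
  if (!is.na(object@maxLag) && object@maxLag < 1)
    msg <- c(msg, "maxLag must be >= 1 (or NA for automatic)")
  if (length(msg)) msg else TRUE
})
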