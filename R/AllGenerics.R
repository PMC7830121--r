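#' @include AllClasses.R
NULL

#' Accessors for voxel volumes and masks
#'
#' `voxelData()` returns the raw 3D array, `voxelSpacing()` the per-axis
#' voxel size in mm, `volumeShape()` the voxel counts per axis,
#' `sourceName()` the originating file name. For [BinaryMask-class]
#' objects, `lesionCount()` gives the number of lesion (1) voxels and
#' `thresholdUsed()` the binarization threshold (`NA` if the input was
#' already binary).
#'
#' @param x a [VoxelVolume-class] or [BinaryMask-class].
#' @return see the individual descriptions.
#' @name volume-accessors
#' @aliases voxelData voxelSpacing volumeShape sourceName lesionCount
#'   thresholdUsed
#' @examples
#' m <- bernoulliField(c(8, 8, 8), p = 0.2, seed = 1)
#' volumeShape(m)
#' lesionCount(m)
NULL

#' @rdname volume-accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname volume-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname volume-accessors
#' @export
setGeneric("volumeShape", function(x) standardGeneric("volumeShape"))
#' @rdname volume-accessors
#' @export
setGeneric("sourceName", function(x) standardGeneric("sourceName"))
#' @rdname volume-accessors
#' @export
setGeneric("lesionCount", function(x) standardGeneric("lesionCount"))
#' @rdname volume-accessors
#' @export
setGeneric("thresholdUsed", function(x) standardGeneric("thresholdUsed"))

#' @rdname volume-accessors
setMethod("voxelData", "VoxelVolume", function(x) x@data)
#' @rdname volume-accessors
setMethod("voxelSpacing", "VoxelVolume", function(x) x@spacing)
#' @rdname volume-accessors
setMethod("volumeShape", "VoxelVolume", function(x) dim(x@data))
#' @rdname volume-accessors
setMethod("sourceName", "VoxelVolume", function(x) x@sourceName)
#' @rdname volume-accessors
setMethod("lesionCount", "BinaryMask", function(x) x@lesionVoxelCount)
#' @rdname volume-accessors
setMethod("thresholdUsed", "BinaryMask", function(x) x@thresholdUsed)

#' Accessors for empirical variograms and model fits
#'
#' `lagDirection()` returns the axis (`"x"`, `"y"`, `"z"`); `lagsVoxels()`
#' the integer lags; `lagDistances()` the lag distances in mm;
#' `semivariance()` the gamma values; `pairCounts()` the pair counts
#' n(h). For [ExpModelFit-class]: `modelRange()` the fitted range a (mm),
#' `modelSill()` the fitted sill c, `fitRSS()` the residual sum of
#' squares and `isConverged()` the convergence flag.
#'
#' @param x an [EmpiricalVariogram-class] or [ExpModelFit-class].
#' @return see the individual descriptions.
#' @name variogram-accessors
#' @aliases lagDirection lagsVoxels lagDistances semivariance pairCounts
#'   modelRange modelSill fitRSS isConverged
NULL

#' @rdname variogram-accessors
#' @export
setGeneric("lagDirection", function(x) standardGeneric("lagDirection"))
#' @rdname variogram-accessors
#' @export
setGeneric("lagsVoxels", function(x) standardGeneric("lagsVoxels"))
#' @rdname variogram-accessors
#' @export
setGeneric("lagDistances", function(x) standardGeneric("lagDistances"))
#' @rdname variogram-accessors
#' @export
setGeneric("semivariance", function(x) standardGeneric("semivariance"))
#' @rdname variogram-accessors
#' @export
setGeneric("pairCounts", function(x) standardGeneric("pairCounts"))
#' @rdname variogram-accessors
#' @export
setGeneric("modelRange", function(x) standardGeneric("modelRange"))
#' @rdname variogram-accessors
#' @export
setGeneric("modelSill", function(x) standardGeneric("modelSill"))
#' @rdname variogram-accessors
#' @export
setGeneric("fitRSS", function(x) standardGeneric("fitRSS"))
#' @rdname variogram-accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname variogram-accessors
setMethod("lagDirection", "EmpiricalVariogram", function(x) x@direction)
#' @rdname variogram-accessors
setMethod("lagsVoxels", "EmpiricalVariogram", function(x) x@lags)
#' @rdname variogram-accessors
setMethod("lagDistances", "EmpiricalVariogram", function(x) x@distances)
#' @rdname variogram-accessors
setMethod("semivariance", "EmpiricalVariogram", function(x) x@gamma)
#' @rdname variogram-accessors
setMethod("pairCounts", "EmpiricalVariogram", function(x) x@pairCounts)
#' @rdname variogram-accessors
setMethod("lagDirection", "ExpModelFit", function(x) x@direction)
#' @rdname variogram-accessors
setMethod("modelRange", "ExpModelFit", function(x) x@a)
#' @rdname variogram-accessors
setMethod("modelSill", "ExpModelFit", function(x) x@c)
#' @rdname variogram-accessors
setMethod("fitRSS", "ExpModelFit", function(x) x@rss)
#' @rdname variogram-accessors
setMethod("isConverged", "ExpModelFit", function(x) x@converged)

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s: %d x %d x %d voxels, spacing %s mm  [%s]\n",
              class(object), d[1], d[2], d[3],
              paste(format(object@spacing), collapse = " x "),
              object@sourceName))
  if (is(object, "BinaryMask"))
    cat(sprintf("  lesion voxels: %d (%.4f%% of volume), threshold: %s\n",
                object@lesionVoxelCount,
                100 * object@lesionVoxelCount / prod(d),
                ifelse(is.na(object@thresholdUsed), "none",
                       format(object@thresholdUsed))))
  invisible(NULL)
})

setMethod("show", "EmpiricalVariogram", function(object) {
  cat(sprintf(
    "EmpiricalVariogram (direction %s): %d lags, %.3g-%.3g mm\n",
    object@direction, length(object@lags),
    min(object@distances), max(object@distances)))
  print(data.frame(lag = object@lags, distance_mm = object@distances,
                   gamma = object@gamma, pairs = object@pairCounts),
        row.names = FALSE)
  invisible(NULL)
})

setMethod("show", "ExpModelFit", function(object) {
  if (object@converged)
    cat(sprintf(
      "ExpModelFit (direction %s): a = %.5g mm, c = %.5g, rss = %.3g (%d lags)\n",
      object@direction, object@a, object@c, object@rss, object@nPoints))
  else
    cat(sprintf("ExpModelFit (direction %s): NOT converged (%s)\n",
                object@direction, object@message))
  invisible(NULL)
})

setMethod("show", "LDPRecord", function(object) {
  cat(sprintf("LDPRecord %d [%s]: ln(mean a) = %.5f, ln(mean c) = %.5f\n",
              object@id, object@filename, object@lnMeanA, object@lnMeanC))
  comp <- rbind(`ln(a)` = object@lnA, `ln(c)` = object@lnC)
  print(round(comp, 5))
  invisible(NULL)
})
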