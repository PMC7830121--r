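#' @include AllClasses.R
NULL

# run code under a fixed seed without disturbing the caller's RNG
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic i.i.d. Bernoulli lesion field
#'
#' Generates a [BinaryMask-class] whose voxels are independently 1 with
#' probability `p`. For such a field the expected semivariance is
#' p (1 - p) at every positive lag, which makes it the analytic test
#' field for the variography: the empirical variogram must scatter
#' around that flat sill within sampling error.
#'
#' @param shape integer(3), voxel counts per axis.
#' @param p lesion probability per voxel, in \[0, 1\].
#' @param seed integer seed; the generator is a pure function of
#'   (shape, p, seed) and restores the caller's RNG state.
#' @param spacing numeric(3), voxel size in mm.
#' @return a [BinaryMask-class].
#' @examples
#' m <- bernoulliField(c(16, 16, 16), p = 0.5, seed = 1)
#' mean(semivariance(empiricalVariogram(m, "x", 4)))  # near 0.25
#' @export
bernoulliField <- function(shape, p, seed, spacing = c(1, 1, 1)) {
  stopifnot(length(shape) == 3L, all(shape >= 2), p >= 0, p <= 1)
  b <- .withSeed(seed,
    array(as.numeric(stats::runif(prod(shape)) < p), dim = shape))
  new("BinaryMask", data = b, spacing = as.numeric(spacing),
      sourceName = sprintf("bernoulli_p%g_seed%d", p, as.integer(seed)),
      lesionVoxelCount = as.integer(sum(b)), thresholdUsed = NA_real_)
}

#' Synthetic ellipsoidal lesion scene
#'
#' Builds a binary mask as the union of `nLesions` ellipsoids with the
#' given semi-axes (mm) at seeded random centers, mimicking a
#' white-matter lesion mask with controllable size, load and anisotropy
#' (e.g. semi-axes stretched in z produce a larger fitted range along
#' z). Ellipsoids are clipped at the volume bounds; no wrap-around.
#'
#' @param shape integer(3), voxel counts per axis.
#' @param nLesions number of ellipsoids (0 gives an all-zero mask).
#' @param radiusMm numeric(3), semi-axes (rx, ry, rz) in mm, or a
#'   nLesions x 3 matrix of per-lesion semi-axes.
#' @param seed integer seed for the center placement.
#' @param spacing numeric(3), voxel size in mm.
#' @param margin fraction of each axis kept free of centers at either
#'   end (placement jitter spans the rest), default 0.1.
#' @return a [BinaryMask-class].
#' @examples
#' m <- ellipsoidScene(c(32, 32, 32), nLesions = 5,
#'                     radiusMm = c(2, 2, 6), seed = 3)
#' lesionVolumeFraction(m)
#' @export
ellipsoidScene <- function(shape, nLesions, radiusMm, seed,
                           spacing = c(1, 1, 1), margin = 0.1) {
  stopifnot(length(shape) == 3L, all(shape >= 2), nLesions >= 0,
            margin >= 0, margin < 0.5)
  if (is.matrix(radiusMm)) {
    stopifnot(nrow(radiusMm) == nLesions, ncol(radiusMm) == 3L)
    radii <- radiusMm
  } else {
    stopifnot(length(radiusMm) == 3L)
    radii <- matrix(radiusMm, nrow = max(nLesions, 1L), ncol = 3L,
                    byrow = TRUE)
  }
  if (any(radii <= 0)) stop("semi-axes must be strictly positive")
  spacing <- as.numeric(spacing)
  extent <- shape * spacing
  b <- array(0, dim = shape)
  if (nLesions > 0) {
    centers <- .withSeed(seed, {
      lo <- margin * extent
      hi <- (1 - margin) * extent
      matrix(stats::runif(3 * nLesions,
                          rep(lo, each = nLesions),
                          rep(hi, each = nLesions)),
             ncol = 3L)
    })
    # voxel centers at (i - 0.5) * spacing
    coords <- lapply(1:3, function(ax) (seq_len(shape[ax]) - 0.5) * spacing[ax])
    for (l in seq_len(nLesions)) {
      ctr <- centers[l, ]
      r <- radii[l, ]
      idx <- lapply(1:3, function(ax) {
        which(abs(coords[[ax]] - ctr[ax]) <= r[ax])
      })
      if (any(lengths(idx) == 0)) next
      u <- lapply(1:3, function(ax) (coords[[ax]][idx[[ax]]] - ctr[ax]) / r[ax])
      q <- outer(outer(u[[1]]^2, u[[2]]^2, "+"), u[[3]]^2, "+")
      inside <- q <= 1
      b[idx[[1]], idx[[2]], idx[[3]]][inside] <- 1
    }
  }
  new("BinaryMask", data = b, spacing = spacing,
      sourceName = sprintf("ellipsoids_n%d_seed%d", as.integer(nLesions),
                           as.integer(seed)),
      lesionVoxelCount = as.integer(sum(b)), thresholdUsed = NA_real_)
}

#' Lesion volume fraction of a mask
#'
#' Fraction of voxels that are lesion (value 1). For a Bernoulli(p)
#' field this estimates p; for lesion scenes it is the total lesion
#' load, the quantity the fitted sill is a proxy of.
#'
#' @param mask a [BinaryMask-class].
#' @return numeric(1) in \[0, 1\].
#' @export
lesionVolumeFraction <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  mask@lesionVoxelCount / prod(dim(mask@data))
}

#' Brute-force directional variogram (reference implementation)
#'
#' Literal transcription of the semivariance definition with explicit
#' loops over every voxel pair: for each lag k, walk all (i, j, l) and
#' accumulate (z(s) - z(s + k e_dir))^2 over pairs that stay inside the
#' array. Identical contract to [empiricalVariogram()]; it exists as an
#' independent reference for validating the vectorized path and is far
#' too slow for production volumes.
#'
#' @inheritParams empiricalVariogram
#' @param maxLag number of one-voxel lags.
#' @return an [EmpiricalVariogram-class].
#' @export
bruteForceVariogram <- function(mask, direction = c("x", "y", "z"),
                                maxLag) {
  stopifnot(is(mask, "BinaryMask"))
  direction <- match.arg(direction)
  shape <- dim(mask@data)
  maxLag <- .checkLagSpec(maxLag, shape, direction)
  ax <- .AXIS_INDEX[[direction]]
  x <- mask@data
  gamma <- numeric(maxLag)
  pairs <- numeric(maxLag)
  for (k in seq_len(maxLag)) {
    ss <- 0; n <- 0
    for (i in seq_len(shape[1])) for (j in seq_len(shape[2]))
      for (l in seq_len(shape[3])) {
        tgt <- c(i, j, l)
        tgt[ax] <- tgt[ax] + k
        if (tgt[ax] > shape[ax]) next
        dd <- x[i, j, l] - x[tgt[1], tgt[2], tgt[3]]
        ss <- ss + dd * dd
        n <- n + 1
      }
    gamma[k] <- ss / (2 * n)
    pairs[k] <- n
  }
  new("EmpiricalVariogram", direction = direction,
      lags = seq_len(maxLag),
      distances = seq_len(maxLag) * mask@spacing[ax],
      gamma = gamma, pairCounts = pairs)
}
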