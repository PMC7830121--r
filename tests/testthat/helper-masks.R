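# build domain objects directly from arrays, bypassing file I/O
asMask <- function(arr, spacing = c(1, 1, 1), name = "synthetic") {
  new("BinaryMask", data = array(as.numeric(arr), dim = dim(arr)),
      spacing = as.numeric(spacing), sourceName = name,
      lesionVoxelCount = as.integer(sum(arr)), thresholdUsed = NA_real_)
}

asVolume <- function(arr, spacing = c(1, 1, 1), name = "synthetic") {
  new("VoxelVolume", data = array(as.numeric(arr), dim = dim(arr)),
      spacing = as.numeric(spacing), sourceName = name)
}

randomMask <- function(shape, seed, p = 0.5, spacing = c(1, 1, 1)) {
  bernoulliField(shape, p = p, seed = seed, spacing = spacing)
}

# synthetic empirical variogram with prescribed gamma values
syntheticVariogram <- function(gamma, distances = seq_along(gamma),
                               direction = "x") {
  new("EmpiricalVariogram", direction = direction,
      lags = seq_along(gamma), distances = as.numeric(distances),
      gamma = as.numeric(gamma),
      pairCounts = rep(1000, length(gamma)))
}

convergedFit <- function(direction, a, c) {
  new("ExpModelFit", direction = direction, a = a, c = c, rss = 0,
      converged = TRUE, nPoints = 10L, message = "")
}

# record whose mean columns are derived from the per-direction logs
recordFromComponents <- function(id, lnA, lnC, filename) {
  names(lnA) <- names(lnC) <- c("x", "y", "z")
  new("LDPRecord", id = as.integer(id),
      lnMeanA = log(mean(exp(lnA))), lnMeanC = log(mean(exp(lnC))),
      lnA = lnA, lnC = lnC, filename = filename)
}

# three seeded ellipsoid scenes of graded severity, written as NIfTI
writeSceneInputs <- function(dir, shape = c(48, 48, 48)) {
  vapply(1:3, function(i) {
    m <- ellipsoidScene(shape, nLesions = 3 * i,
                        radiusMm = c(1.5, 1.5, 1.5) + 0.5 * i,
                        seed = 100 + i)
    p <- file.path(dir, sprintf("scene_%d.nii", i))
    writeMask(m, p)
    p
  }, character(1))
}

pngDims <- function(path) {
  d <- dim(png::readPNG(path))
  c(width = d[2], height = d[1])
}
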