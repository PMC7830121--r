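test_that("NIfTI round trip preserves data, shape and spacing exactly", {
  m <- bernoulliField(c(8, 8, 8), p = 0.4, seed = 2,
                      spacing = c(1.5, 1.5, 1.5))
  f <- file.path(tempdir(), "roundtrip.nii")
  writeMask(m, f)
  v <- loadVolume(f)
  expect_identical(volumeShape(v), c(8L, 8L, 8L))
  expect_equal(voxelSpacing(v), c(1.5, 1.5, 1.5))
  expect_identical(voxelData(v), voxelData(m))
  b <- binarize(v, 0.5)
  expect_identical(voxelData(b), voxelData(m))
  expect_identical(lesionCount(b), lesionCount(m))
})

test_that("Analyze-7.5 pairs are readable via either member", {
  skip_if_not_installed("oro.nifti")
  a <- array(as.numeric(runif(6 * 5 * 4) > 0.6), c(6, 5, 4))
  img <- oro.nifti::anlz(a, datatype = 16)
  img@pixdim <- c(0, 1.2, 1.2, 1.2, 0, 0, 0, 0)
  stem <- file.path(tempdir(), "anlzpair")
  suppressWarnings(oro.nifti::writeANALYZE(img, stem, gzipped = FALSE))
  for (member in paste0(stem, c(".hdr", ".img"))) {
    v <- suppressWarnings(loadVolume(member))
    expect_identical(volumeShape(v), c(6L, 5L, 4L))
    # Analyze headers store pixdim as float32
    expect_equal(voxelSpacing(v), c(1.2, 1.2, 1.2), tolerance = 1e-6)
    expect_equal(voxelData(v), a)
  }
})

test_that("non-3D volumes are rejected; trailing singletons are squeezed", {
  img4 <- RNifti::asNifti(array(runif(4 * 4 * 4 * 2), c(4, 4, 4, 2)))
  f4 <- file.path(tempdir(), "four_d.nii")
  RNifti::writeNifti(img4, f4)
  expect_error(loadVolume(f4), "not 3D")

  # RNifti normalizes singleton dims on write; oro.nifti keeps the
  # nominally-4D header, which is the case the squeeze handles
  skip_if_not_installed("oro.nifti")
  o <- oro.nifti::nifti(array(runif(4 * 4 * 4), c(4, 4, 4, 1)))
  stem <- file.path(tempdir(), "squeeze")
  oro.nifti::writeNIfTI(o, stem, gzipped = FALSE)
  expect_warning(v <- loadVolume(paste0(stem, ".nii")), "singleton")
  expect_identical(volumeShape(v), c(4L, 4L, 4L))

  expect_error(loadVolume(file.path(tempdir(), "no_such_file.nii")),
               "not found")
})

test_that("binarize uses a strict 'above threshold' rule", {
  v <- asVolume(array(c(0, 0.4, 0.5, 0.6, 1, 0, 0, 0), c(2, 2, 2)))
  b <- binarize(v, 0.5)
  expect_equal(as.vector(voxelData(b))[1:5], c(0, 0, 0, 1, 1))
  expect_identical(lesionCount(b), 2L)
  expect_identical(thresholdUsed(b), 0.5)

  z <- binarize(asVolume(array(0, c(3, 3, 3))), 0.5)
  expect_identical(lesionCount(z), 0L)
})

test_that("binarize is idempotent and monotone in the threshold", {
  set.seed(14)
  v <- asVolume(array(runif(6^3), c(6, 6, 6)))
  b1 <- binarize(v, 0.5)
  b2 <- binarize(asVolume(voxelData(b1)), 0.5)
  expect_identical(voxelData(b1), voxelData(b2))

  counts <- vapply(seq(0, 1, by = 0.1),
                   function(t) lesionCount(binarize(v, t)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("binarize rejects bad thresholds and NaN voxels", {
  v <- asVolume(array(runif(27), c(3, 3, 3)))
  expect_error(binarize(v, 1.5), "\\[0, 1\\]")
  expect_error(binarize(v, -0.1), "\\[0, 1\\]")
  d <- voxelData(v); d[c(1, 5, 9)] <- NaN
  expect_error(binarize(asVolume(d), 0.5), "3 NaN")
})

test_that("domain classes enforce their invariants", {
  expect_error(asVolume(array(0, c(1, 4, 4))), "at least 2")
  expect_error(asMask(array(0.5, c(3, 3, 3))), "exactly 0 or 1")
  expect_error(new("VoxelVolume", data = array(0, c(3, 3, 3)),
                   spacing = c(1, -1, 1), sourceName = "bad"),
               "positive")
})
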