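mniMildRecord <- function() {
  recordFromComponents(1, c(0.30975, 0.40066, 1.01342),
                       c(-9.74533, -9.75081, -9.72945), "MNI_mild.img")
}

test_that("records serialize as tab-delimited rows with 5 decimals", {
  f <- file.path(tempdir(), "serial.var")
  if (file.exists(f)) file.remove(f)
  appendVarRecord(f, mniMildRecord())
  lines <- readLines(f)
  expect_length(lines, 2L)
  expect_match(lines[1], "^ID\t")
  expect_identical(
    lines[2],
    paste("1", "0.62610", "-9.74182", "0.30975", "-9.74533", "0.40066",
          "-9.75081", "1.01342", "-9.72945", "MNI_mild.img", sep = "\t"))
})

test_that(".var files round trip through append and read", {
  f <- file.path(tempdir(), "roundtrip.var")
  if (file.exists(f)) file.remove(f)
  recs <- list(
    mniMildRecord(),
    recordFromComponents(2, c(0.89172, 0.98117, 1.13109),
                         c(-7.58171, -7.63554, -7.56123),
                         "MNI_moderate.img"),
    recordFromComponents(3, c(1.30517, 1.51387, 1.61090),
                         c(-6.47390, -6.57510, -6.49598),
                         "MNI_severe.img"))
  for (r in recs) appendVarRecord(f, r)
  tab <- readVarFile(f)
  expect_identical(tab$ID, 1:3)
  expect_identical(tab$File,
                   c("MNI_mild.img", "MNI_moderate.img", "MNI_severe.img"))
  expect_equal(tab$lnAX, c(0.30975, 0.89172, 1.30517))
  # mean columns are recomputed from the 5-decimal components, so they
  # may differ from the reference in the last serialized digit
  expect_equal(tab$lnMeanA, c(0.62610, 1.00625, 1.48463),
               tolerance = 2e-5)
  # serialized precision is 5 decimals; a reread reproduces it exactly
  f2 <- file.path(tempdir(), "rewrite.var")
  if (file.exists(f2)) file.remove(f2)
  for (i in 1:3)
    appendVarRecord(f2, recordFromComponents(
      i, unlist(tab[i, c("lnAX", "lnAY", "lnAZ")]),
      unlist(tab[i, c("lnCX", "lnCY", "lnCZ")]), tab$File[i]))
  expect_identical(readLines(f2), readLines(f))
})

test_that("malformed .var files are rejected with line numbers", {
  f <- file.path(tempdir(), "broken.var")
  writeLines(character(0), f)
  expect_error(readVarFile(f), "missing header")
  writeLines(c("not", "a", "var file"), f)
  expect_error(readVarFile(f), "missing header")

  ok <- file.path(tempdir(), "ok.var")
  if (file.exists(ok)) file.remove(ok)
  appendVarRecord(ok, mniMildRecord())
  lines <- readLines(ok)
  writeLines(c(lines, "2\t0.1\t0.2"), f)
  expect_error(readVarFile(f), "line\\(s\\) 3")
  writeLines(c(lines, sub("^1\t", "7\t", lines[2])), f)
  expect_error(readVarFile(f), "consecutive")
  expect_error(readVarFile(file.path(tempdir(), "absent.var")),
               "no such")
})

test_that("plot products are valid PNGs at the configured pixel size", {
  skip_if_not_installed("png")
  m <- ellipsoidScene(c(28, 28, 28), 4, c(2, 2, 3), seed = 12)
  emps <- variogramsXYZ(m, 8)
  fits <- lapply(emps, fitExponential)
  f <- file.path(tempdir(), "vario.png")
  plotVariograms(emps, fits, f, width = 640, height = 480)
  expect_equal(pngDims(f), c(width = 640, height = 480))

  vf <- file.path(tempdir(), "plots.var")
  if (file.exists(vf)) file.remove(vf)
  appendVarRecord(vf, mniMildRecord())
  tab <- readVarFile(vf)
  before <- tab
  p1 <- file.path(tempdir(), "ldp.png")
  p2 <- file.path(tempdir(), "ldp_xyz.png")
  plotLDP(tab, p1, width = 500, height = 400)
  plotComponentLDP(tab, p2, width = 500, height = 400)
  expect_equal(pngDims(p1), c(width = 500, height = 400))
  expect_equal(pngDims(p2), c(width = 500, height = 400))
  expect_identical(tab, before)  # plotting never mutates the table
})

test_that("points outside the standardized span are drawn with a warning", {
  r <- recordFromComponents(1, c(3.4, 3.5, 3.6), c(-6, -6, -6),
                            "wide.nii")
  f <- file.path(tempdir(), "span.var")
  if (file.exists(f)) file.remove(f)
  appendVarRecord(f, r)
  tab <- readVarFile(f)
  out <- file.path(tempdir(), "span.png")
  expect_warning(plotLDP(tab, out, width = 400, height = 300),
                 "outside the configured axis span")
  expect_true(file.exists(out))
  expect_error(plotLDP(tab[0, ], out), "empty")
  expect_error(plotComponentLDP(tab[0, ], out), "empty")
})
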