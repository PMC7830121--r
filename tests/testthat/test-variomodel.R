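test_that("the exponential model has the textbook anchor points", {
  expect_equal(exponentialModel(0, a = 2, c = 0.3), 0)
  # practical range: ~95% of the sill at h = a
  expect_equal(exponentialModel(5, a = 5, c = 1), 1 - exp(-3),
               tolerance = 1e-12)
  expect_equal(exponentialModel(1e6, a = 2, c = 0.01), 0.01,
               tolerance = 1e-9)
  expect_error(exponentialModel(1, a = 0, c = 1), "positive")
})

test_that("noiseless model points are recovered essentially exactly", {
  d <- 1:15
  for (a in c(1, 5)) for (cc in c(1e-3, 0.1)) {
    f <- fitExponential(syntheticVariogram(exponentialModel(d, a, cc), d))
    expect_true(isConverged(f))
    expect_equal(modelRange(f), a, tolerance = 1e-8)
    expect_equal(modelSill(f), cc, tolerance = 1e-8)
  }
})

test_that("scaling the semivariances scales the sill and keeps the range", {
  d <- 1:12
  g <- exponentialModel(d, a = 4, c = 0.02)
  f1 <- fitExponential(syntheticVariogram(g, d))
  for (s in c(0.1, 3, 50)) {
    fs <- fitExponential(syntheticVariogram(s * g, d))
    expect_equal(modelRange(fs), modelRange(f1), tolerance = 1e-6)
    expect_equal(modelSill(fs), s * modelSill(f1), tolerance = 1e-6)
  }
})

test_that("degenerate variograms yield a non-converged fit, not an error", {
  f <- fitExponential(syntheticVariogram(rep(0, 10)))
  expect_false(isConverged(f))
  expect_match(f@message, "degenerate")
  expect_true(is.na(modelRange(f)))
  expect_error(fitExponential(syntheticVariogram(c(0.1, 0.2))),
               "at least 3 lags")
})

test_that("custom starting estimates are honoured and bad ones reported", {
  d <- 1:15
  emp <- syntheticVariogram(exponentialModel(d, 5, 0.01), d)
  f <- fitExponential(emp, guessA = 1, guessC = 0.5)
  expect_true(isConverged(f))
  expect_equal(modelRange(f), 5, tolerance = 1e-6)
  expect_false(isConverged(fitExponential(emp, guessA = -2)))
})

test_that("ldpSummary takes the log of the mean, not the mean of the logs", {
  f <- list(convergedFit("x", 2, 1e-3), convergedFit("y", 3, 2e-3),
            convergedFit("z", 10, 3e-3))
  r <- ldpSummary(f, id = 1, filename = "demo.nii")
  expect_equal(r@lnMeanA, log(mean(c(2, 3, 10))))
  expect_equal(r@lnMeanC, log(mean(c(1e-3, 2e-3, 3e-3))))
  expect_equal(unname(r@lnA), log(c(2, 3, 10)))
  # Jensen: for unequal values, log of mean exceeds mean of logs
  expect_gt(r@lnMeanA, mean(r@lnA))
  # equal parameters: both coincide
  fe <- list(convergedFit("x", 4, 1e-3), convergedFit("y", 4, 1e-3),
             convergedFit("z", 4, 1e-3))
  expect_equal(ldpSummary(fe, 2, "eq.nii")@lnMeanA, log(4))
})

test_that("ldpSummary rejects incomplete or non-converged fit sets", {
  bad <- new("ExpModelFit", direction = "z", a = NA_real_, c = NA_real_,
             rss = NA_real_, converged = FALSE, nPoints = 10L,
             message = "singular gradient")
  f <- list(convergedFit("x", 2, 1e-3), convergedFit("y", 3, 2e-3), bad)
  expect_error(ldpSummary(f, 1, "x.nii"), "did not converge.*z")
  expect_error(ldpSummary(f[1:2], 1, "x.nii"), "three")
  expect_error(ldpSummary(list(convergedFit("x", 1, 1), convergedFit("x", 1, 1),
                               convergedFit("y", 1, 1)), 1, "x.nii"),
               "x, y and z")
})

test_that("fits on real variography output feed a valid record", {
  m <- ellipsoidScene(c(32, 32, 32), 5, c(2.5, 2.5, 2.5), seed = 77)
  emps <- variogramsXYZ(m, 10)
  fits <- lapply(emps, fitExponential)
  expect_true(all(vapply(fits, isConverged, logical(1))))
  rec <- ldpSummary(fits, 1, sourceName(m))
  expect_true(validObject(rec))
  # sill of a sparse binary field stays below the Bernoulli bound
  expect_lt(exp(rec@lnMeanC), 0.25)
})
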