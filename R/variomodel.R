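#' @include AllClasses.R
NULL

#' Exponential variogram model
#'
#' Evaluates gamma(h) = c (1 - exp(-3 |h| / a)). With this
#' parameterization `a` is the practical range: the model reaches
#' 1 - exp(-3), about 95%, of the sill `c` at h = a.
#'
#' @param h lag distance(s), mm, >= 0.
#' @param a range, mm, > 0.
#' @param c sill, >= 0.
#' @return model semivariance, same length as `h`.
#' @examples
#' exponentialModel(5, a = 5, c = 1)  # ~0.9502
#' @export
exponentialModel <- function(h, a, c) {
  if (!is.finite(a) || a <= 0)
    stop("range 'a' must be strictly positive")
  c * (1 - exp(-3 * abs(h) / a))
}

#' Fit the exponential model to an empirical variogram
#'
#' Unweighted nonlinear least-squares fit of the exponential variogram
#' model to the (distance, gamma) pairs of one directional empirical
#' variogram, at the positive lags 1..maxLag only (no artificial (0, 0)
#' anchor is added). The optimizer is Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]); parameters are fitted unconstrained and a
#' solution with non-positive range or sill is reported as not
#' converged. Non-convergence never throws: the returned
#' [ExpModelFit-class] carries `converged = FALSE` and a diagnostic
#' message, so a batch over many masks can log and skip.
#'
#' Default starting estimates are scale-free: `guessA` is half the
#' maximum lag distance and `guessC` is the mean semivariance over the
#' upper half of the lags (the plateau region).
#'
#' @param emp an [EmpiricalVariogram-class] with at least 3 finite
#'   gamma values.
#' @param guessA starting estimate of the range, mm (`NULL` = automatic).
#' @param guessC starting estimate of the sill (`NULL` = automatic).
#' @return an [ExpModelFit-class].
#' @examples
#' d <- 1:15
#' g <- exponentialModel(d, a = 5, c = 0.01)
#' emp <- new("EmpiricalVariogram", direction = "x", lags = 1:15,
#'            distances = as.numeric(d), gamma = g,
#'            pairCounts = rep(1000, 15))
#' fitExponential(emp)
#' @export
fitExponential <- function(emp, guessA = NULL, guessC = NULL) {
  stopifnot(is(emp, "EmpiricalVariogram"))
  h <- emp@distances
  g <- emp@gamma
  ok <- is.finite(h) & is.finite(g)
  if (sum(ok) < 3L)
    stop("need at least 3 lags with finite gamma to fit the model")
  h <- h[ok]; g <- g[ok]
  if (is.null(guessA)) guessA <- max(h) / 2
  if (is.null(guessC)) guessC <- mean(g[h > max(h) / 2])

  fail <- function(msg) new("ExpModelFit", direction = emp@direction,
                            a = NA_real_, c = NA_real_, rss = NA_real_,
                            converged = FALSE, nPoints = length(g),
                            message = msg)
  if (!is.finite(guessA) || guessA <= 0)
    return(fail(sprintf("invalid starting range %g", guessA)))
  if (!is.finite(guessC) || guessC <= 0)
    return(fail("degenerate variogram: sill starting estimate is not positive"))

  fit <- tryCatch(
    minpack.lm::nlsLM(g ~ c * (1 - exp(-3 * h / a)),
                      start = list(a = guessA, c = guessC),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = .Machine$double.eps,
                        ptol = .Machine$double.eps)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(fail(conditionMessage(fit)))
  p <- stats::coef(fit)
  if (!all(is.finite(p)) || p[["a"]] <= 0 || p[["c"]] <= 0)
    return(fail(sprintf(
      "solution outside the admissible region (a = %g, c = %g)",
      p[["a"]], p[["c"]])))
  new("ExpModelFit", direction = emp@direction,
      a = unname(p[["a"]]), c = unname(p[["c"]]),
      rss = sum(stats::resid(fit)^2), converged = TRUE,
      nPoints = length(g), message = "")
}

#' Summarize three directional fits as one LDP record
#'
#' Combines the x, y, z exponential-model fits of one lesion mask into
#' the log-scale coordinates of the discrimination plot:
#' \deqn{\bar a = \ln(\mathrm{mean}(a_X, a_Y, a_Z)), \quad
#'       \bar c = \ln(\mathrm{mean}(c_X, c_Y, c_Z)),}
#' the natural log of the arithmetic mean (not the mean of the logs),
#' together with the per-direction log components.
#'
#' @param fits list of three converged [ExpModelFit-class] objects, in
#'   x, y, z order (as returned by fitting [variogramsXYZ()] output).
#' @param id 1-based integer index of the input file in its batch.
#' @param filename source file name stored in the record.
#' @return an [LDPRecord-class].
#' @examples
#' mk <- function(d, a, c) new("ExpModelFit", direction = d, a = a, c = c,
#'   rss = 0, converged = TRUE, nPoints = 15L, message = "")
#' ldpSummary(list(mk("x", 1.5, 1e-4), mk("y", 1.6, 1e-4),
#'                 mk("z", 2.5, 1e-4)), id = 1, filename = "demo.nii")
#' @export
ldpSummary <- function(fits, id, filename) {
  if (length(fits) != 3L || !all(vapply(fits, is, TRUE, "ExpModelFit")))
    stop("'fits' must be a list of three ExpModelFit objects")
  dirs <- vapply(fits, function(f) f@direction, character(1))
  if (!setequal(dirs, c("x", "y", "z")))
    stop("fits must cover the x, y and z directions")
  fits <- fits[order(match(dirs, c("x", "y", "z")))]
  bad <- !vapply(fits, function(f) isTRUE(f@converged), TRUE)
  if (any(bad))
    stop("cannot summarize: fit did not converge in direction(s) ",
         paste(vapply(fits[bad], function(f) f@direction, character(1)),
               collapse = ", "),
         " (", paste(vapply(fits[bad], function(f) f@message,
                            character(1)), collapse = "; "), ")")
  a <- vapply(fits, function(f) f@a, numeric(1))
  cc <- vapply(fits, function(f) f@c, numeric(1))
  names(a) <- names(cc) <- c("x", "y", "z")
  new("LDPRecord", id = as.integer(id),
      lnMeanA = log(mean(a)), lnMeanC = log(mean(cc)),
      lnA = log(a), lnC = log(cc),
      filename = filename)
}
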