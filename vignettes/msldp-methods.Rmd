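---
title: "Variogram-based discrimination of white-matter lesion patterns"
author: "msldp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variogram-based discrimination of white-matter lesion patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msldp)
```

## The model

A binary white-matter lesion mask in a standardized brain space is a
3D indicator field: `z(x) = 1` inside lesions, `0` elsewhere. Its
spatial structure is captured by the empirical semivariance

$$\gamma(h) = \frac{1}{2\,n(h)} \sum_{i=1}^{n(h)} \big(z(x_i) - z(x_i+h)\big)^2,$$

evaluated along each of the three grid axes at integer voxel lags
`h = 1..maxLag`. For an indicator field $\gamma(h)$ is the probability
that two voxels at separation $h$ disagree, halved, so it is bounded
by $p(1-p) \le 1/4$ where $p$ is the lesion volume fraction. Small
$\gamma$ at small lags means strong short-range correlation — large,
smooth lesions; the level at which the curve flattens reflects how
much lesion there is overall.

Each directional variogram is quantified by the exponential model

$$\gamma(h) = c\,\big(1 - e^{-3|h|/a}\big),$$

parameterized so that the range $a$ (mm) is the *practical* range: the
model attains $1 - e^{-3} \approx 95\%$ of the sill $c$ at $h = a$.
The three directional fits are condensed to the discrimination-plot
coordinates

$$\bar a = \ln \mathrm{mean}(a_X, a_Y, a_Z), \qquad
  \bar c = \ln \mathrm{mean}(c_X, c_Y, c_Z),$$

the log of the arithmetic mean. This is deliberately *not* the mean of
the logs: for unequal directional parameters the two differ (Jensen's
inequality), and the tabulated reference values are only reproduced by
the log-of-mean form. `ldpSummary()` implements it and the
`LDPRecord` validity check enforces it.

Assumptions worth stating: masks are already segmented and spatially
normalized (the package performs neither); array axes are taken as the
anatomical x/y/z as stored, without reorientation from the header
affine (a warning is issued if the header carries a rotation); and the
whole array — background zeros included — is the variography domain,
because the mask definition makes every non-lesion voxel a valid 0.
No brain cropping is applied.

## Tunable parameters

* **`imageThreshold`** (default 0.5, dimensionless): probability maps
  are binarized by the strict rule `value > threshold` — "above the
  threshold" — so a voxel exactly at the threshold is background.
  Binarization is idempotent and monotone in the threshold.
* **`maxLag`** (default automatic): one-voxel-wide distance classes.
  The automatic choice confines lags to 15 mm on the coarsest axis,
  `floor(15 / max(spacing))` — 15 lags for 1 mm voxels, 10 for
  1.5 mm — because the diagnostic correlation structure of lesion
  masks lives within roughly 0–15 mm; beyond that the empirical curve
  mostly reiterates the sill.
* **`guessA`, `guessC`** (default automatic): starting estimates for
  the nonlinear fit. The defaults are scale-free — half the maximum
  lag distance for the range, and the mean semivariance over the upper
  half of the lags (the plateau region) for the sill — and converge
  for every synthetic and phantom case exercised by the test suite.
  Both can be overridden to chase replication of runs made with other
  start values.
* **Axis spans** of the plots (defaults $\bar a \in [0,3]$,
  $\bar c \in [-12,-4]$): a cohort-derived plotting convention, kept
  as overridable defaults. Points outside the span are still drawn,
  with a warning, rather than silently dropped.
* **Plot size** (default 1200×900 px) and the per-file variogram plot
  postfix (default `_variograms.png`) are free styling parameters.

## Numerical choices

*Variography* is computed by shifted-array differences: lag `k` along
an axis compares the array with itself offset by `k`, which on a
regular grid is exactly the set of axis-aligned pairs — no angular
tolerance is involved, and edge pairs are simply absent (no padding or
wrap-around). The pair count at lag `k` along an axis with `n` voxels
is therefore `(n - k)` times the product of the other two axis
lengths, which the `EmpiricalVariogram` tests assert for every lag. A
literal pair-loop transcription of the defining sum,
`bruteForceVariogram()`, ships with the package as an independent
reference; the vectorized path must agree with it bit-exactly, and the
production code never calls it. Distances use the spacing of the lag
axis, so anisotropic voxels give each direction its own distance grid
(the geostatistically correct reading when voxels are not cubes).

*Fitting* minimizes the unweighted least-squares objective over the
positive lags only; no artificial `(0, 0)` anchor is appended, and no
pair-count weighting is applied (a deliberate mirror of a plain
`nls`-style fit; weighting would change the estimates). The optimizer
is Levenberg–Marquardt (`minpack.lm::nlsLM`) because the
Gauss–Newton relative-offset criterion of plain `nls` is unreliable on
(near-)zero-residual problems, and exact recovery of noiseless model
points is part of the package's validation contract. Parameters are
fitted unconstrained; a solution with non-positive range or sill — as
arises for an empty mask, whose variogram is identically zero — is
reported as `converged = FALSE` rather than clamped. Fit failures
never throw: a batch over a cohort logs the reason, skips the file and
keeps the remaining IDs consecutive.

*Serialization*: the `.var` container is tab-delimited ASCII with a
fixed 10-column header, numbers written with 5 decimal places and an
ASCII hyphen-minus. Mean columns re-derived from the serialized
5-decimal components can therefore differ from the originals in the
last digit; the round-trip tests account for exactly that precision.

## What the synthetic generators emulate

`bernoulliField()` produces i.i.d. indicator noise with known
analytics: $E[\gamma(h)] = p(1-p)$ at every positive lag. The
acceptance checks test the observed $\gamma$ against this value within
3 standard errors, computed exactly for an i.i.d. field — including
the covariance of within-row pairs that share a voxel, which the
naive independent-pairs (binomial) formula omits and which matters at
$p \ne 0.5$.

`ellipsoidScene()` builds unions of ellipsoids with given semi-axes at
seeded random centers: exactly binary, crisp-boundaried blobs like
thresholded lesion masks, with controllable size (range should grow
with radius), load (sill should grow with volume fraction) and
anisotropy (stretching the z semi-axis should raise $a_Z$ above
$a_X, a_Y$). These orderings are what the property tests assert.

What the generators do **not** emulate: real lesion morphology
(periventricular confluence, Dawson fingers, cortical proximity),
partial-volume effects, segmentation noise, or the spatial
inhomogeneity of real lesion probability. Passing the synthetic tests
therefore validates the *estimator chain* — variography, model fit,
log-scale summary, serialization — not any clinical claim about real
cohorts. The one regression against real reference data, the
three-phantom table reproduced within ±0.05 on the ln scale, requires
the publicly downloadable BrainWeb MS phantoms (binary volumes not
shipped with the package) under `tests/testthat/brainweb/`; the test
states this and fails until they are provided. The seeded generators
live entirely in the fixtures layer: the analysis pipeline itself
contains no random state, and two identical runs produce byte-identical
`.var` files.

## Problem sizes

The test suite runs on volumes chosen to keep the full suite in the
tens of seconds while leaving no estimator path untested: pair-loop
equivalence on 30 random masks up to 8³ (where the brute-force
reference is affordable), Bernoulli analytics on 64³ fields, scene
ladders and end-to-end pipeline runs on 48³ scenes with 3–16
ellipsoidal lesions. Production masks in 1 mm standard space
(181×217×181) process in well under a minute per volume with the
default 15 lags.

## Known limitations

* Only axis-aligned directional variograms are computed — no
  omnidirectional variogram, variogram maps, or oblique directions —
  and only the exponential model is fitted; model selection is out of
  scope.
* Voxels exactly equal to the binarization threshold are assigned to
  background by the strict rule; data containing exact ties straddle
  implementations that use `>=`.
* Header affines are not applied, so inputs must already be in a
  consistent axis convention; mixing radiological/neurological
  orderings across a cohort will silently swap x-direction parameters.
* The sill is a lesion-load *proxy* bounded by $p(1-p)$; at very high
  lesion fractions it saturates and loses sensitivity.
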