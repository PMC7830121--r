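# msldp — lesion pattern discrimination plots from directional variograms

Multiple sclerosis produces highly variable patterns of white-matter
lesions, and summarizing a complex 3D lesion configuration in a way
that supports follow-up and cross-sectional comparison is hard. `msldp`
does this with two-point geostatistics: it treats a binary lesion mask
(1 = lesion, 0 = everything else) in standard Montreal Normal Brain
space as a spatial indicator field and condenses each mask to two
log-scale coordinates that can be compared across patients, time points
and cohorts. It is aimed at neuroimaging researchers who already have
segmented, spatially normalized lesion masks (or lesion probability
maps) in NIfTI-1 or Analyze-7.5 format.

## The method

For a mask `z(x) ∈ {0, 1}` the **directional empirical variogram**
along each grid axis is

    γ(h) = 1 / (2 n(h)) · Σᵢ ( z(xᵢ) − z(xᵢ + h) )²

where `h` runs over integer voxel lags (converted to mm with the voxel
spacing of that axis) and `n(h)` counts all axis-aligned voxel pairs at
that separation. Every voxel participates; pairs that would leave the
array are simply not formed. Lags are confined to ~0–15 mm by default,
the distance band that carries the relevant correlation structure.

Each directional variogram is then fitted (unweighted nonlinear least
squares) with the **exponential variogram model**

    γ(h) = c · ( 1 − exp(−3 |h| / a) )

whose **range `a`** (mm — the distance where the model reaches ~95% of
its plateau) measures spatial continuity: the larger `a`, the bigger
and smoother the lesions. The **sill `c`** (the plateau) is a proxy of
total lesion load. The three directional fits `(aX, cX), (aY, cY),
(aZ, cZ)` are combined by the *log of the arithmetic mean* (not the
mean of the logs),

    ā = ln(mean(aX, aY, aZ)),   c̄ = ln(mean(cX, cY, cZ)),

giving one point per lesion pattern on the **discrimination plot**
(axes standardized to ā ∈ [0, 3], c̄ ∈ [−12, −4]). The **component
plot** shows the per-direction pairs `(ln a_d, ln c_d)` instead and
reveals anisotropy, e.g. lesions stretched along z.

## Worked example

Three synthetic lesion scenes of graded severity, processed end to end:

```r
library(msldp)
td <- tempdir()
inputs <- vapply(1:3, function(i) {
  m <- ellipsoidScene(c(48, 48, 48), nLesions = 3 * i,
                      radiusMm = c(1.5, 1.5, 1.5) + 0.5 * i, seed = 100 + i)
  p <- file.path(td, sprintf("scene_%d.nii", i)); writeMask(m, p); p
}, character(1))
cfg <- ldpConfig(inputs, file.path(td, "scenes.var"),
                 file.path(td, "scenes_LDP.png"),
                 file.path(td, "scenes_LDP_xyz.png"))
report <- runPipeline(cfg)
readVarFile(file.path(td, "scenes.var"))
```

prints

```
[1/3] scene_1.nii
    a(x,y,z) = 5.761/7.409/8.232 mm; c(x,y,z) = 0.00102/0.00118/0.00122
[2/3] scene_2.nii
    a(x,y,z) = 7.759/5.929/7.456 mm; c(x,y,z) = 0.00437/0.00381/0.0043
[3/3] scene_3.nii
    a(x,y,z) = 6.408/7.734/9.397 mm; c(x,y,z) = 0.0091/0.0102/0.0108
wrote .../scenes.var (3 record(s)), .../scenes_LDP.png, .../scenes_LDP_xyz.png
  ID lnMeanA  lnMeanC    lnAX     lnCX    lnAY     lnCY    lnAZ     lnCZ        File
1  1 1.96482 -6.77633 1.75105 -6.88405 2.00266 -6.74275 2.10798 -6.71055 scene_1.nii
2  2 1.95272 -5.48207 2.04882 -5.43275 1.77988 -5.56990 2.00897 -5.44909 scene_2.nii
3  3 2.06006 -4.60437 1.85758 -4.69979 2.04562 -4.58965 2.24042 -4.53094 scene_3.nii
```

Reading the table: the fitted ranges sit around 6–9 mm (lesion
diameters of a few millimetres, `lnMeanA ≈ 2`), and `lnMeanC` climbs
from −6.8 to −4.6 as the lesion load grows from scene 1 to scene 3 —
the sill tracks lesion volume fraction, which is exactly what the
discrimination plot uses to separate mild from severe patterns. The
`.var` file is a tab-delimited ASCII table (5 decimals) that other
tools can consume directly; the two PNGs are the discrimination plot
and its per-direction component plot, and each input additionally gets
a `<name>_variograms.png` showing the three directional variograms
(red/green/blue = x/y/z) with their fitted models.

A command-line front-end wrapping the same pipeline is installed at
`system.file("scripts", "ldpgen.R", package = "msldp")`:

```sh
Rscript ldpgen.R --inputs "MNI_mild.hdr,MNI_moderate.hdr,MNI_severe.hdr" \
  --var-out MNI.var --ldp-out MNI_LDP.png --component-out MNI_LDP_xyz.png
```

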