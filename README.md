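# hsvreg

Automatic band-to-band registration of in vivo hyperspectral
microvasculature image cubes, and downstream blood-oxygen-saturation
(SO2) mapping.

A hyperspectral vessel cube is a stack of narrow-band images of the same
tissue acquired sequentially. Because acquisition takes seconds, the
specimen drifts between bands; any per-pixel spectral analysis (such as
oximetry) is meaningless until every band is resampled into a common
frame. `hsvreg` does this fully automatically and validates itself
against a synthetic phantom with exact ground truth.

## Method

1. **Segmentation.** Each band is thresholded with a windowed Otsu rule:
   the image is tiled, Otsu's threshold is computed per tile, and a tile's
   threshold is only *applied* if its between-class variance exceeds a
   fixed fraction of the global between-class variance — tiles without
   bimodal evidence inherit the global threshold. A curvature-regularized
   level-set-style contour filter then removes small clutter and smooths
   vessel boundaries.

2. **Features and matching.** Scale- and rotation-aware interest points
   are detected on the binary vessel masks (determinant-of-Hessian on a
   distance-transform representation) and matched between adjacent bands
   by nearest-neighbour descriptor distance with a Lowe ratio test and a
   mutual-best cross-check.

3. **Cycle-consistent chain filtering.** Pairwise matches are composed
   into chains across all bands. For any chain, the loop-closing residual
   is propagated through the per-link rotations,

   `r_closure = R_ki R_jk r_ij + R_ki r_jk + r_ki`,

   and the triangle inequality bounds its norm by three times the
   per-link bound ε for a 3-cycle. Chains whose closure residual exceeds
   a threshold δ are discarded as outliers; the survivors feed a
   robust (trimmed least-squares) rigid fit per band.

4. **Resampling and evaluation.** The cube is warped into the reference
   band's frame. Registration quality is measured by directional errors
   `Ex`/`Ey` of tracked feature positions and by the mean per-band
   standard deviation of spectra inside a 6×6 homogeneous vessel ROI,
   which collapses when the bands align.

5. **Oximetry.** SO2 is mapped two ways: closed-form dual-wavelength
   Beer–Lambert inversion against tabulated HbO2/Hb extinction spectra,
   and blind end-member extraction (alternating simplex-constrained
   abundance and end-member updates with an optional mean-shrinkage
   regularizer ρ) for when the pure spectra are unknown.

## Worked example

Everything below is actual output from the installed package.

```r
library(hsvreg)

# A ground-truthed synthetic cube: drifting vessel scene, 10 bands
spec <- phantomSpec(seed = 1L)
ph <- generatePhantom(spec)
ph$cube
#> HyperCube: 10 bands x 128 x 128 px, 12-bit
#>   wavelengths: 550.0-1000.0 nm

# Estimate band-to-band rigid transforms from the cube alone
est <- estimateCubeTransforms(ph$cube)
est$stats
#> $raw
#> [1] 47
#> $retained
#> [1] 10
#> $incomplete
#> [1] 37
#> $delta
#> [1] 10

# Compare the estimates against the known truth, per band
err <- sapply(seq_len(nBands(ph$cube)), function(b) {
  te <- est$transformSet@transforms[[b]]
  tt <- ph$truth@trueTransforms[[b]]
  c(px  = sqrt(sum((te@translation - tt@translation)^2)),
    deg = abs(transformAngle(te) - transformAngle(tt)) * 180 / pi)
})
round(err, 3)
#>     [,1]  [,2]  [,3]  [,4]  [,5]  [,6]  [,7]  [,8]  [,9] [,10]
#> px     0 0.429 0.121 0.144 0.171 0.187 0.282 0.043 0.371 0.407
#> deg    0 0.208 0.003 0.007 0.038 0.027 0.152 0.034 0.155 0.180

# Resample, then check that spectra inside a vessel ROI tighten up
reg   <- registerCube(ph$cube, est$transformSet)
masks <- registerMasks(est$masks, est$transformSet)
roi <- hsvreg:::.autoRoi(getBand(masks, 1L))
c(mean_sd_before = spectralSpread(ph$cube, roi)$mean_sd,
  mean_sd_after  = spectralSpread(reg, roi)$mean_sd)
#> mean_sd_before  mean_sd_after
#>      218.29122       50.91317

# Dual-wavelength SO2 on the registered cube (phantom's own extinction)
lb <- c(2L, 5L)
bg <- vapply(seq_len(nBands(reg)), function(b)
  median(getBand(reg, b)[!getBand(masks, b)]), numeric(1))
ab <- absorbance(reg, bg)
so2 <- so2DualWavelength(ab[lb[1], , ], ab[lb[2], , ], spec$extinction,
                         ph$cube@wavelengths[lb[1]],
                         ph$cube@wavelengths[lb[2]])
summary(as.numeric(so2@values[getBand(masks, 1L)]))
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.0000  0.6533  0.7422  0.7274  0.8101  1.0000
median(abs(so2@values - ph$truth@so2)[getBand(masks, 1L) &
                                      ph$truth@vesselMask])
#> [1] 0.005
```

The recovered SO2 quartiles (0.65 / 0.74 / 0.81) match the ground-truth
field, and the median per-pixel error inside the vessels is 0.005
saturation units.

## Command line

The same pipeline is scriptable via `inst/cli/hsvreg.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "hsvreg.R", package = "hsvreg"))')
Rscript "$CLI" simulate --out sim --seed 1
Rscript "$CLI" run --input sim/cube.bsq --out results
```

Subcommands `segment`, `register`, `evaluate` and `oxymap` run the
individual stages; composing them produces byte-identical artifacts to
`run`. Exit codes: 0 success, 2 usage error, 3 missing input, 4 runtime
failure.

## Tests

```r
testthat::test_dir("tests/testthat", package = "hsvreg",
                   load_package = "installed")
```

The suite includes an acceptance file (`test-acceptance.R`) asserting,
among other criteria: exact agreement of the Otsu implementation with an
exhaustive-search oracle, sub-pixel/sub-half-degree transform recovery on
the default phantom, complete rejection of planted chain outliers with
≥95 % inlier retention, and a 1e-10 SO2 forward/inverse round trip.

## Reproduction

`scripts/acceptance.R` re-derives the cycle-closure bound empirically
against the *installed* package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It simulates 1000 random 3-band rigid cycles with per-link residual
norms at most ε and writes the worst closure-residual norm in multiples
of ε as JSON. The triangle-inequality bound predicts a value of at most
3; with `--seed 1` the observed value is 2.545297.
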