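# dsaflow

Automatic hemodynamic analysis of dynamic digital subtraction angiography
(DSA).

In patients with carotid stenosis, the interesting quantity is not the
anatomy of the stenosis but how long blood takes to transit the brain.
Interventionists read this off the angiogram they already have — without
extra contrast or radiation — either manually (the **cerebral circulation
time**, CCT: the time-to-peak difference between a parietal-vein ROI and a
cavernous internal-carotid ROI on a lateral run) or, with this package,
fully automatically: the **angiographic mean transit time** (aMTT), a
parenchymal transit measure that tracks MR-perfusion MTT, computed per view
as aMTT_AP and aMTT_Lat.

dsaflow is aimed at researchers in neurovascular imaging who want that
pipeline as auditable, reproducible building blocks, with a synthetic
phantom that gives every stage a known ground truth.

## The method

Given a subtraction frame stack on the clinical multi-rate grid
(7.5 fps x 5 s, 4 fps x 3 s, 3 fps x 2 s, 2 fps x 2 s; 12 s base):

1. **Motion correction** — each frame is rigidly aligned (keypoint
   consensus + sub-pixel Gauss–Newton refinement) and composed back to the
   t = 0 reference coordinates.
2. **FastICA** — frames, permuted to 1-D pixel signals, are decomposed into
   exactly three independent source images with per-frame mixing weights:
   arterial, capillary and venous phases, labelled by time-to-peak order.
3. **Otsu masking** — the capillary spatial map is binarized at the
   between-class-variance-maximizing threshold.
4. **TDC + gamma-variate fit** — the masked, registered series yields the
   capillary time–density curve C(t), fitted by
   `C(t) = baseline + K (t − t₀)^α exp(−(t − t₀)/β)` for `t > t₀`,
   with TTP = t₀ + αβ and FWHM = β·w(α) exactly.
5. **aMTT** — the FWHM of the fitted capillary curve, per view.

CCT is computed from user-supplied ROI polygons/masks
(`cavernous_ICA`, `parietal_vein`) as TTP(vein) − TTP(artery).

## Worked example

Generate a phantom whose capillary FWHM is exactly 5 s, then run the full
pipeline:

```r
library(dsaflow)

ph <- generatePhantom(standardPhantom("easy", seed = 42))
ph$series
#> DSASeries: 60 frames of 128 x 128 (LAT view)
#>   time grid: 0.000 .. 11.500 s (median dt 0.133 s)
#>   density range: [0, 1.683]

entry <- computeAMTT(ph$series, seed = 1)
entry$aMTT_s
#> [1] 4.998293
entry$fit
#> GammaVariateFit: t0 0.870 s, alpha 2.999, beta 1.210 s, K 0.2132, baseline 2.404e-05
#>   TTP 4.499 s, FWHM 4.998 s, R^2 1.0000
```

The fitted arrival time, shape and scale reproduce the phantom's capillary
kinetics (t₀ = 0.868, α = 3, β = 1.2107); the reported aMTT of 4.998 s
recovers the constructed 5.00 s FWHM to 0.03%. The intermediates — the
`ComponentSet` with its three time courses, the Otsu `VesselMask`, the
capillary `TDC`, the per-frame transforms — are all returned in `entry`
for audit.

CCT from ROIs on a lateral run:

```r
res <- computeCCT(ph$series, readROIs("rois.json"))
res
#> CCT: 5.000 s (TTP vein 7.000 s - TTP artery 2.000 s, argmax)
```

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/dsaflow.R synth --standard easy --seed 42 --out phantom/
Rscript inst/cli/dsaflow.R analyze --input phantom/stack.npy \
    --timestamps phantom/timestamps.json --view LAT --seed 7 --out results/
```

`results/report.json` carries `aMTT_AP` / `aMTT_Lat`, fit parameters,
`cct_s` when ROIs were given, and full provenance (seed, version, config
hash); TDCs, component maps, masks and transforms are written alongside.

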