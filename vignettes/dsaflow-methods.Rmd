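---
title: "Automatic flow analysis of dynamic DSA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic flow analysis of dynamic DSA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsaflow)
```

dsaflow turns a dynamic digital subtraction angiography (DSA) run into two
quantitative hemodynamic markers. The **angiographic mean transit time**
(aMTT) is extracted fully automatically: the frame stack is motion-corrected,
decomposed by independent component analysis into arterial, capillary and
venous phases, the capillary phase is segmented by Otsu thresholding, and the
full width at half maximum (FWHM) of the capillary time--density curve (TDC)
under a gamma-variate fit is reported, per view (aMTT_AP, aMTT_Lat). The
**cerebral circulation time** (CCT) follows the manual workflow: the
time-to-peak (TTP) difference between an ROI on the parietal vein and one on
the cavernous internal carotid artery on a lateral angiogram. This vignette
documents the models, the parameters that matter, the numerical choices, and
what the synthetic phantom does and does not establish.

## The acquisition model

Cranial DSA bolus runs are acquired on a multi-rate schedule: fast early
frames while the arterial bolus transits, slower frames through the
parenchymal and venous phases. The default schedule is 7.5 frames/s for
5 s, then 4 fps for 3 s, 3 fps for 2 s and 2 fps for 2 s — a 12 s base
acquisition, optionally prolonged at 2 fps when venous opacification is
slow:

```{r}
ts <- buildTimeGrid(defaultSchedule())
length(ts); range(ts)
```

Each segment is half-open `[start, start + duration)`: a frame falls exactly
on a segment's start, never on its end. The convention matters because
7.5 fps x 5 s is not an integer frame count; under the half-open rule the
first segment holds 38 frames (t = 0 ... 37/7.5 s) and the default grid 60.
All downstream fitting works on this non-uniform grid directly — curves are
never resampled.

Densities are held in the canonical polarity "larger value = more iodine",
with the t = 0 reference frame ~0 everywhere. Readers accept an `invert`
flag (subtraction angiograms conventionally render contrast dark) and
subtract the t = 0 frame by default. Supported containers are NPY stacks and
multi-page TIFF plus a timestamps JSON; DICOM export must be converted
upstream, since no DICOM reader is available to the package.

## Motion correction

Patient motion between subtraction frames displaces vessels across pixels
and corrupts every downstream TDC. The correction model is rigid (rotation
+ translation): head motion over a 12 s cranial run is well approximated as
rigid, and two-and-a-half parameters per frame stay estimable even on
frames with little anatomy.

A subtracted series poses two specific problems. First, the natural
reference — the frame at t = 0 — is empty by construction, so there is
nothing to match against it directly. Second, appearance changes completely
between early (arterial) and late (venous) frames, so a single reference
cannot serve the whole run. The implementation therefore aligns each frame
to its *predecessor* — the only pair guaranteed to share appearance — and
composes the relative transforms back to the reference coordinates.
Contrast-free frames contribute identity links, which is also the correct
physical statement that their alignment is unobservable.

Each relative transform is estimated in two stages:

1. **Keypoint consensus** (used when the relative motion is large): Harris
   corners, patch descriptors normalized to the dominant local gradient
   orientation, Lowe ratio-test matching at 0.75, and a RANSAC rigid fit
   with 1 px inlier tolerance, refit on the inliers.
2. **Sub-pixel refinement**: Gauss--Newton minimization of
   $\| g \cdot M(S x) - R(x) \|^2$ over rotation, translation and a free
   gain $g$ that absorbs the frame-to-frame change in contrast amplitude.
   The refinement rejects any solution that does not reduce the residual of
   its initializer, and implausibly large frame-to-frame motion is replaced
   by an identity link.

On the motion phantom (translations to 4 px, rotations to 1.5 degrees,
onset after contrast arrival — patients hold still at injection and react
to the bolus sensation) the chained estimate recovers the injected motion
with a mean residual displacement below 0.1 px, and restores the aMTT that
uncorrected analysis biases low.

## Phase separation by ICA

The decomposition treats each 2-D frame, permuted into a 1-D pixel signal,
as a mixture of exactly three statistically independent **source images**:
the arterial tree, the capillary blush, the venous drainage. The per-frame
mixing weights of each source form its time course. This orientation —
spatial sources, temporal mixing — is deliberate. Distinct vascular
territories overlap little *in space*, so their mean-removed maps are close
to independent, and the mixing weights (the physiologic bolus curves) are
left unconstrained. The alternative, temporal sources, fails structurally:
the three phases' bolus curves overlap heavily *in time* and are strongly
correlated, while whitening forces estimated sources to be uncorrelated, so
no rotation of a whitened temporal basis can reproduce them.

Estimation is standard symmetric fixed-point FastICA: per-frame mean
removal, PCA whitening to exactly three directions, log-cosh contrast,
tolerance 1e-4, at most 500 iterations, with the random orthogonal start
drawn from a caller-supplied seed — the only stochastic element of the
whole pipeline, which makes end-to-end runs bit-reproducible. Rank-deficient
input (fewer informative directions than components) is flagged on the
result rather than raised, and the trailing components are returned as
zeros.

Two ambiguities that ICA cannot resolve are fixed by convention:

* **Sign**: each component is flipped so that its time course's maximum
  exceeds the magnitude of its minimum — a contrast bolus increases
  density. The paired map flips too, leaving the reconstruction unchanged.
* **Phase labels**: components are ordered by the time of their
  time-course peak; earliest is arterial, middle capillary, latest venous.
  Ties fall to spatial-map energy (the stronger map takes the earlier
  phase), then to component index, with a warning.

A known failure mode at severe carotid stenosis is stagnant arterial flow
mimicking capillary kinetics, so that arteries leak into the capillary
component. The capillary TDC is therefore screened for two distinguishable
peaks (local maxima above 40% of the amplitude separated by a valley below
70% of the lower peak) and a warning is attached to the result when the
pattern appears. On the bundled stress phantom — arterial washout slowed
until the arterial and capillary courses correlate at about 0.87, with the
blush shifted onto the arterial tree — the spatial-source decomposition in
fact still separates the compartments cleanly; the screen exists for the
harder mixtures real anatomy produces.

## Vessel masks and time--density curves

The capillary (and other) spatial maps are binarized with Otsu's method:
values are histogrammed into 256 equal-width bins over their range and the
bin edge maximizing the between-class variance is chosen, computing class
means from the actual values so that the result is identical to an
exhaustive search over all candidate edges; ties return the lowest edge.
Negative map weights are clipped to zero first — under the sign convention
only positive loading marks contrast arrival. A constant map yields a
*flagged degenerate* mask rather than an error, and the pipeline marks the
affected view invalid.

The TDC is extracted by masking the registered series — the measurement
comes from the data, not from the ICA model — and averaging the masked
pixels per frame. The mean (not the sum) keeps curves comparable between
views and mask sizes; the FWHM is invariant to vertical scaling either way.

## Gamma-variate kinetics, TTP, FWHM

Bolus passage is modelled by the indicator-dilution gamma-variate

$$C(t) = \mathrm{baseline} + K\,(t - t_0)^{\alpha} e^{-(t - t_0)/\beta},
\qquad t > t_0,$$

with $C(t) = \mathrm{baseline}$ before arrival. Two exact identities anchor
the implementation and its tests: the peak falls at
$\mathrm{TTP} = t_0 + \alpha\beta$, and the FWHM factorizes as
$\beta\, w(\alpha)$ with $w$ depending only on the shape — so the FWHM is
independent of amplitude and baseline and exactly linear in $\beta$.
$w(\alpha)$ is evaluated by bisection on each side of the peak of
$x^{\alpha} e^{-x}$, to an interval below 1e-9.

Fitting is nonlinear least squares on the non-uniform grid with uniform
weights (each frame is one measurement; the varying frame rate implies no
duration weighting). Initialization scans ~25 candidate arrival times
between 0 and the sample peak; at each candidate the model is
log-linearized, $\log(C - b_0) = \log K + \alpha \log(t-t_0) - (t-t_0)/\beta$,
and solved linearly; the best candidate seeds a Levenberg--Marquardt
refinement of all five parameters with $\alpha, \beta$ bounded positive.
The baseline is a free parameter: curves arrive baseline-subtracted, and a
free offset absorbs residual background. Preconditions are enforced
loudly — at least 8 samples, a peak at least 3 robust noise s.d. (estimated
from first differences) above baseline, not still rising at the last
sample — and a warning marks fits with $R^2 < 0.8$.

The aMTT is the FWHM of the *fitted* capillary curve, not of the raw
samples: at 2 fps late in the run, raw half-crossings are quantized to
0.5 s, while the fit interpolates the crossing times on the analytic curve.
TTP for the CCT defaults to the sample argmax (mirroring the manual
workflow it replaces, with ties resolved to the earliest time plus a
warning); a fitted TTP is exposed as an option and is what the phantom
validation uses when sub-frame accuracy matters.

Cohort-level reporting (`correlateMarkers`) computes pairwise Pearson
correlations with raw two-sided p-values flagged at 0.05, without
multiplicity correction; no verbal strength labels are attached to r
values.

## The synthetic phantom

Every stage above is validated against a phantom whose truth is known by
construction. Compartments (vessel polylines with width, blush ellipses;
unit coordinates, so phantoms are resolution-independent) carry
gamma-variate kinetics and add where they overlap, as projection physics
dictates. Static lognormal per-pixel amplitude jitter (sigma 0.15) gives
Otsu realistic non-binary maps; Gaussian noise is calibrated as a fraction
of the noiseless global peak; rigid per-frame motion can be scheduled; and
everything is a deterministic function of one seed.

The standard layouts use 128 x 128 frames on the default 60-frame schedule
(a size at which the full pipeline runs in seconds), TTPs of 2 / 4.5 / 7 s
for the three phases, peak amplitudes 1.0 / 0.5 / 0.8 (the blush is
dimmer than vessels), and a capillary shape fixed at $\alpha = 3$ with
$\beta = 5/w(3)$ so the true capillary FWHM is exactly 5 s. Named variants:
`easy` (disjoint compartments), `overlap` (the blush shifted so ~20% of
arterial pixels are overlapped), `severe_stenosis_like` (arterial kinetics
slowed to the stress condition above), `motion` (easy plus bounded rigid
motion). Biplane testing uses two independent geometry layouts (AP, LAT)
sharing kinetics — sufficient to validate per-view aMTT without 3-D
ray-casting.

What the phantom does *not* emulate bounds what green tests mean: no real
anatomy or overlapping bone, no X-ray physics (beam hardening, scatter),
no deformable motion, no vessel-specific flow profiles, and compartment
kinetics that are exactly gamma-variate — the model being fitted. Passing
recovery tests therefore demonstrates correctness of the machinery, not
clinical accuracy on patient data.

## Numerical and interface choices

* Pixel coordinates are 0-based `(x = column, y = row)`; ROI polygons are
  filled by the even-odd rule over pixel centres; rotation is about the
  image centre. Bilinear interpolation everywhere; pixels mapped from
  outside the frame get zero density.
* The Monte-Carlo checks in the test-suite and acceptance script use 100
  seeded realizations at 5% noise on the standard 128 x 128 x 60 phantom;
  medians are compared, so occasional fit failures (flagged, below 5%)
  do not mask a systematic bias.
* Reports embed seed, package version, parameters and a config hash;
  identical inputs and seed give byte-identical reports.
* A single series with one frame, constant frames, all-negative maps,
  flat TDCs and rank-deficient stacks all follow the contracts above:
  flagged or raised, never silent.

## Known limitations

DICOM must be converted externally. The registration chain accumulates
sub-pixel error over very long prolonged runs (drift is a random walk in
the link errors; negligible at 60-80 frames). The phase labelling assumes
the three TTPs are distinct by at least about two frame intervals — heavily
shunted circulations (e.g. arteriovenous fistulae) violate this and are
outside scope. The two-peak screen detects bimodal admixture but no
remedial unmixing is attempted; affected runs should fall back to manual
ROI reading.
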