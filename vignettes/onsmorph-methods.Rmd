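---
title: "Methods: optic nerve and sheath morphometry with onsmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optic nerve and sheath morphometry with onsmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onsmorph)
```

`onsmorph` quantifies two MRI-derived descriptors of the optic nerve (ON)
and its CSF-filled sheath (ONS): *ON deviation*, a tortuosity proxy
computed from an operator-picked nerve centerline, and the *ON/ONS
cross-sectional areas* 3 mm posterior to the ON head, extracted
semi-automatically from coronal T2-weighted volumes. Because clinical and
astronaut imaging data of this kind are access-restricted, the package
ships a digital phantom generator with analytic ground truth, and the
reliability estimators used to characterize repeated measurements. This
vignette explains the models, the tunable parameters, the numerical
choices, and the limits of what the phantom-based validation shows.

## ON deviation

The nerve path is supplied as an ordered list of 3D points in mm
(anterior to posterior), typically picked every 1–2 mm on multiplanar
reconstructions, with the ON head as the distinguished starting point. The
statistic is

> the maximum orthogonal distance between the curved centerline and the
> straight line joining the ON head to the point 20 mm posterior along the
> trajectory.

Pipeline (`computeDeviation()`): an interpolating cubic spline is fit
through the picked points — chord-length parameterized, one `splinefun`
per coordinate — sampled every `sampleStepMm` (default 0.1 mm, well below
the ~0.5 mm in-plane resolution of the source scans, so discretization
error is negligible); the sampled curve is truncated at `lengthMm`
(default 20 mm) of cumulative chordal arc length, interpolating the final
point inside its segment; the distance is measured to the *infinite* line
through the chord endpoints, which for interior points equals the segment
distance and keeps the statistic continuous.

Design points that were genuinely open:

- **Arc length, not Euclidean distance**, defines the 20 mm endpoint:
  "trajectory length" denotes path length, and for curved nerves the two
  differ (a 20 mm arc of radius 50 mm has a 19.87 mm chord).
- **Interpolating, not smoothing, spline.** No smoothing parameter is
  specified by the method's description; interpolation is reproducible,
  and operator jitter is treated as a reliability question rather than
  filtered away. Consequence, quantified by the Monte-Carlo fixtures: the
  maximum-distance statistic over an interpolated noisy path is biased
  upward by roughly the jitter SD (≈ +0.17 mm at 0.2 mm jitter on a 50 mm
  arc). A smoothing spline would trade this for a geometry-dependent
  downward bias.
- **The maximum is taken over the sampled spline**, not the raw picks —
  the denser curve is the object the statistic describes.
- If the ON head is supplied separately from the first path point it is
  prepended before fitting (the chord is anchored at the head); a 1 mm
  snap tolerance guards against mislabeled inputs.

Correctness anchors: a straight path gives 0; a planar arc of radius `R`
truncated at 20 mm gives the sagitta `R(1 − cos(10/R))` (verified to
1e-3 mm for R from 15 to 100 mm against closed form and a dense
brute-force oracle); the statistic is rigid-motion invariant to 1e-6 mm.

## Adaptive-threshold segmentation

Coronal T2-like volumes (12-bit intensities, 0–4095; default spacing
0.253 × 0.253 × 0.600 mm) are processed slice by slice
(`measureVolume()`):

1. **Background estimation** (`estimateBackground()`). The orbital-fat
   background mean `B_s` is the mean intensity within ±10% of the
   intensity range around the histogram peak. The unit-bin histogram of a
   noisy slice has too few counts per bin to define a stable peak, so the
   counts are smoothed with a moving average (default 1% of the range)
   before peak-picking; with that choice the estimate moves by <2
   intensity units across noise realizations at SNR 20 on a 256×256
   slice.
2. **Threshold** (`computeThreshold()`). `T = C + (B̄ − B_s)` with `B̄`
   the cohort-mean background and `C` a common value. `C` is the one
   genuinely free constant of the method; for the phantom intensities the
   default 1850 is the midpoint of fat (700) and CSF (3000), and real
   cohorts must set it explicitly. The literal sign convention above is
   the default; because it arguably moves the threshold the wrong way for
   dim scans, a `brightness_tracking` alternative
   (`T = C + (B_s − B̄)`) is provided, and the convention in force is
   recorded in the output provenance.
3. **Cubic upsampling** (`upsampleSlice()`). Separable Catmull-Rom
   (Keys, a = −0.5) convolution, default factor 4 (≈63 µm effective
   pixel). Boundary taps use linearly extrapolated virtual samples so
   linear ramps are reproduced exactly everywhere; step-edge over/
   undershoot is bounded by the kernel constant 2/27. Original pixel
   centers keep their mm coordinates (0-based indices, voxel-center
   convention).
4. **Iso-contouring** (`extractContours()`). Marching-squares contours at
   level `T` via `grDevices::contourLines`, in physical mm. Pieces split
   where the level passes exactly through a grid node are stitched back
   into loops; chains that terminate on the image border are discarded.
5. **Selection** (`selectOnOnsContours()`). Survivors of a point-count
   filter (≥20 vertices at the contouring resolution — a *minimum*, the
   natural reading of a filter against tiny noise loops) and a roundness
   filter (isoperimetric quotient `Q = 4πA/P² ≥ 0.6`, which rejects
   elongated vessel-like contours at roughly 4:1 aspect) are searched for
   a nested pair — outer containing the inner's centroid, centroids
   within half the inner equivalent radius — preferring the roundest
   inner member. In T2 contrast the CSF between nerve and sheath is
   bright, so inner = ON boundary, outer = ONS boundary.
6. **Interpolation at 3 mm** (`interpolateContourAtOffset()`). The target
   plane is the ON-head axial position + 3 mm along the slice axis — an
   approximation to "along the nerve trajectory" that is accurate because
   the bulbar segment is near-straight over 3 mm. Bracketing slices'
   contours are resampled to 128 radii by angle about their centroids and
   centroid + radii are blended linearly by axial weight ("shape" mode);
   an "area" mode blends the scalar areas instead as a cross-check. The
   angular representation assumes star-shaped contours, valid for the
   near-elliptical sections seen here.
7. **Readout.** Areas by the shoelace formula; equivalent diameters
   `d = 2√(A/π)` under a circular cross-section assumption.

Slices failing selection are dropped (they must still bracket the target
plane); every accepted slice must satisfy ON area < ONS area.

### Sensitivity to the free constant

Because the partial-volume edge is one in-plane voxel wide, sweeping `T`
across a fraction *q* of the fat–CSF contrast displaces the contour by
*q*·253 µm radially, changing the ONS area by about `2πr·q·0.253` mm²
(≈7.5% for the middle half of the contrast, <5% for the middle quarter).
This bound is part of the test suite; it is the irreducible
threshold-sensitivity of a one-voxel edge, not an implementation artifact.

## Digital phantom

`idealizedPhantom()` renders concentric tubes — sheath outer diameter
tapering linearly 7 → 5 mm over a 20 mm axial length, nerve 3.35 mm —
at the acquisition resolution. Voxel values are partial-volume means
obtained by 3× supersampling per axis; noise is Rician (magnitude MRI:
`|v + n₁ + i n₂|`), with SNR defined as CSF mean / σ. Intensities
(fat 700, nerve 500, CSF 3000) are conventional T2-like contrast
ordering (CSF ≫ fat > nerve), not a physical simulation — no bias
fields, no k-space, no material model of a printed phantom.
`subjectLikePhantom()` perturbs the sheath radius with seeded Fourier
harmonics k = 2–4, `r(θ,z) = R(z) + Σ aₖ cos(kθ + φₖ)`, whose ground-truth
area is the closed form `πR² + (π/2)Σaₖ²`; the perturbation is rejected if
it could reach the nerve. `deviationFixture()` emulates operator picks on
arcs of known sagitta with seeded Gaussian jitter.

What passing phantom tests show — and do not show: they validate the
geometry pipeline (sub-2% area recovery noise-free, sub-5% at SNR 20, a
recovered taper slope of −0.1 mm/mm) under ideal contrast and simple
shapes. They do not establish accuracy on real orbits, where the sheath
boundary abuts other structures, contrast varies biologically, and the
background is not a single tissue.

## Reliability statistics

For a complete cases × repeats table: `consensusDifferences()` reports
mean and SD of absolute deviations from each case's mean (the consensus
is taken as truth since no gold standard exists), in units and as
percentages; `cvRepeats()` averages per-case SD/mean (reported as a
fraction); `icc()` implements the ANOVA variance-components estimators,
default ICC(2,1) — two-way random effects, absolute agreement, single
measurement — with a one-way form available. Sample (n−1) SDs are used
throughout, the small-sample convention. A zero-variance table is defined
to have ICC 1.

The ICC moment estimator is a ratio of mean squares with few degrees of
freedom in small designs and is biased downward there: with 4 cases × 3
raters and variance components 4/1/1 (population ICC 2/3) its mean over
simulations is ≈0.57; the bias decays with the case count (≈0.665 at 24
cases). The package reports the estimator as defined rather than a
bias-corrected variant; reliability tables with very few cases should be
read accordingly.

`phantomReliabilityStudy()` is the digital analog of scanning a physical
phantom twice: a panel of six geometries — three idealized tubes with
wide-end diameters 6.5/7.0/7.5 mm and three subject-like tubes with
irregularity 0.2/0.3/0.4 mm — each rendered twice at SNR 20 with
independent noise seeds and processed identically. The geometries differ
across cases deliberately: between-case variance is what an ICC measures,
mirroring a phantom with multiple distinct inserts. At these conditions
the between-scan ONS area differences have SD ≈ 0.06 mm² and the ICC
exceeds 0.999. To keep runtimes modest the study processes the axial
window 1.2–4.8 mm around the measurement plane; the full-volume pipeline
is exercised separately in the test suite.

## Degenerate inputs and tie-breaks

Contours require ≥3 distinct vertices, nonzero shoelace area, and
simplicity (O(n²) segment test at user construction; marching-squares
output is simple by construction and skips the check). Contours are
normalized counter-clockwise; areas are absolute values. Centerlines
require ≥3 distinct consecutive points; fewer than 4 points fall back to
piecewise-linear fitting with a warning. Paths shorter than the requested
truncation length are rejected with the available length. If several
nested contour pairs survive selection, the pair with the roundest inner
contour wins. Volumes with intensities above 4095 are rescaled to the
12-bit convention on load, with a message.

## Problem sizes used in validation

The test suite and the reliability study use the full-resolution
reference phantom (49 × 49 × 34 voxels) for end-to-end checks, a
coarsened variant (0.4/0.4/1.0 mm spacing) for unit-level fixtures, a
256×256 single-purpose render for the background-stability check, 1000–
2000 replicates for estimator-recovery simulations, and 40–100 seeds for
the jitter Monte Carlo. These sizes make each property measurable with
comfortable margin while keeping the default check fast.
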