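---
title: "Methods: two-view depth-camera densitometry in bodyscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-view depth-camera densitometry in bodyscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Densitometric body-composition analysis needs total body volume (BV): whole-body
density is mass over volume, and the two-compartment Siri equation converts
density to percent body fat. Reference BV instruments (air-displacement
plethysmography, "Bod Pod") are accurate but expensive and stationary. A pair
of consumer infrared depth cameras facing each other across a standing subject
— one anterior, one posterior, each about 1.9 m away — is a far cheaper
alternative: each camera delivers an IR intensity image and a depth image, the
body silhouette is segmented from the IR frame and fused with the depth frame,
the two masked-depth images are back-projected to 3D point clouds, registered,
meshed, and the mesh volume is the raw BV estimate. A linear calibration
against a reference instrument absorbs the systematic error of the
reconstruction, and a regression on sex, physical activity, height and
calibrated BV yields fat mass.

`bodyscan` implements this pipeline end to end, together with a synthetic
scene generator (no scan data from the original study is publicly available)
and the concordance statistics used to validate such systems: intraclass
correlation, Bland–Altman agreement, coefficient of variation and best-subsets
regression.

## Scene model and synthetic data

The generator renders solid-primitive phantoms (spheres, ellipsoids, capsules,
cylinders) of *known* volume through an ideal pinhole model of a Kinect
v2-class camera: 512 × 424 pixels, focal length 365 px, principal point at
(256, 212). Ground-truth volume is analytic for provably disjoint parts and
comes from dense voxelization (2 mm default) otherwise. The standing-adult
preset — head sphere, neck and shoulder capsules, torso ellipsoid, two arm and
two leg capsules — has about 72 L at default dimensions; stature and a radial
`bulk` factor span roughly 35–110 L, covering an adult cohort.

Geometry choices the device literature does not fix, declared here once:

* **World frame**: right-handed, +y up, origin at the centre of the standing
  platform. Cameras sit at (0, 1.1, ±1.9) m with *horizontal* optical axes
  facing each other through the body axis. (A camera aimed at the floor-level
  origin would tilt 27.8° down and clip a standing adult's head outside the
  30.1° vertical half field of view, so "facing each other at chest height"
  is the only geometry that frames the body.)
* **Depth convention**: depth images store camera-z in millimetres
  (0 = no return), the convention under which the pinhole back-projection
  `x = (u − cx)z/fx, y = (v − cy)z/fy` is exact; this is also what the real
  sensor reports.
* **Platform model**: the highly reflective standing platform (0.8 × 0.7 m,
  0.3 m tall) is bright in IR but returns *no depth* — reflective saturation
  — which is precisely what makes it separable from the feet. Its painted
  purpose in the protocol is to separate feet from floor; its pixels must not
  enter the body volume.
* **Noise model**: per-camera Gaussian depth noise (mm) followed by Bernoulli
  dropout to 0, both driven by a single integer seed. Rendering is a pure
  function of (phantom, cameras, platform, seed); identical calls are
  bit-identical.

What the generator does *not* emulate: multi-path IR artefacts, lens
distortion, motion, clothing and hair (the acquisition protocol removes those
with a swim cap and tight swimsuit), and soft-tissue articulation. Passing
tests on these scenes therefore demonstrates the correctness of the geometry
and statistics pipeline, not robustness to every artefact of real hardware.

## Segmentation

Thresholding (Otsu on the IR histogram by default) plus region growth: pixels
at or above `threshold × (1 − 0.25)` form the candidate foreground, and the
single 8-connected component containing the seed — by default the centroid of
the brightest candidate blob not touching the bottom image rows — is kept.
Platform removal applies two rules: bright pixels in the bottom half of the
frame with no depth return are dropped (the saturation signature), and any
remaining bottom-contiguous component whose median depth differs from the leg
depth by more than 120 mm is dropped. Morphological opening/closing with disc
elements (radii 1 and 2 px), small-component removal (64 px) and a
keep-largest rule (ties: smallest row-major first pixel) finish the mask;
cleaning is idempotent. On noiseless synthetic frames the segmented silhouette
equals the renderer's true body-hit mask pixel for pixel.

## Registration

Back-projected clouds are already expressed in the world frame through the
known camera extrinsics, so registration nominally starts at the identity and
ICP refines the residual. Two findings shaped the implementation:

* **Opposed views share almost no surface.** A perspective camera sees a
  convex body only up to `acos(r/d)` from the view axis, so the two
  silhouette rims are separated by a physically never-observed lateral band
  (≈ 2r²/d, about 3 cm at the torso). Measured on the noiseless humanoid,
  only 0.35% of points have a counterpart within 5 mm.
* **Every data-driven criterion prefers collapse.** Trimmed point-to-point,
  Geman–McClure, truncated least squares and inlier counting are all
  *improved* by sliding the posterior shell ~7 cm into the anterior one — the
  shells genuinely fit better interpenetrating. The stand-off axis is simply
  not observable from the geometry.

The implementation therefore treats the extrinsic calibration as a Bayesian
prior, not a mere initial guess: trimmed point-to-plane ICP (linearized 6-DoF
updates) with a normal-compatibility gate (anti-facing matches are never
genuine), a coarse-to-fine correspondence cutoff, and step acceptance under a
truncated-quadratic objective plus a transform prior (pipeline default
σ = 5 mm, 0.5°). For ordinary overlapping clouds the prior defaults to
infinity and the solver behaves as plain trimmed ICP; a constructed 5°/2 cm
motion between copies of a cloud is recovered to < 1e-4 degrees and < 1e-5 m.
Point-to-point (closed-form Kabsch updates) remains selectable.

## Normals and surface reconstruction

Per-point normals come from PCA over 30 nearest neighbours. Orientation uses
the *visibility constraint* — a point's normal must face the camera that
observed it — carried as per-point viewpoints through downsampling, merging
and ICP. (The generic fallback, seeding away from the component centroid and
propagating consistency over the kNN graph, mis-oriented ~40% of normals
across the sparse rim gaps of two-shell clouds; visibility orientation is
exact for projective data and is what practitioners use for RGB-D clouds.)

Reconstruction solves for a smoothed indicator function χ on a uniform grid:
oriented normals are splatted trilinearly into a vector field V, the Poisson
equation ∇²χ = ∇·V is solved spectrally (FFT with a Gaussian pre-smoother,
σ = 1.4 cells), and the isosurface at the mean of χ over the samples is
extracted by **marching tetrahedra** (each cube split into six tetrahedra
around its main diagonal — a conforming split, so the mesh is watertight and
consistently oriented by construction, with no case tables to transcribe).
`poisson_depth` plays the role of an octree depth: the grid spans the cloud's
padded bounding box with 2^depth cells along its largest side; depth 8 ≈ 7 mm
voxels on an adult. Components under 1% of the dominant surface area
(low-support extrapolation far from data) are trimmed, and global orientation
is fixed by the sign of the signed volume.

The two-view geometry cannot observe the lateral band; the Poisson solve
bridges it smoothly. This adds volume — the noiseless humanoid reads
+0.5–3% high — and is deliberately *not* corrected geometrically: it is the
systematic error the calibration regression absorbs, mirroring how the
physical system's raw error (several percent) is corrected to ~0.1% by
fitting against the reference instrument.

Mesh utilities: divergence-theorem volume (|Σ det(v₀,v₁,v₂)|/6, exact 1000 L
on the unit cube), watertightness/orientation audit (every undirected edge on
exactly two faces, each directed edge once), component filtering, fan-fill
hole repair, and Taubin λ/μ smoothing (0.5/−0.53; volume change well under
1%, unlike plain Laplacian shrinkage).

## Densitometry layer

* **Replicate rule**: BV is measured at least twice; if the first two differ
  by more than max(150 mL, 0.3% of the pair mean) a third is required, and
  the closest pair is averaged. The 0.3% base is interpreted as the pair
  mean (the protocol does not state it); with ≥3 values the closest pair is
  always used (ties: pair mean nearest the overall median, then earliest
  indices). Verified against brute-force pair enumeration.
* **Siri constants**: 495/450, the standard two-compartment values; the
  protocol invokes the equation without printing constants, so they are
  config-exposed.
* **Calibration**: OLS of reference on raw volume; fitted values have zero
  mean residual on the fitting set by construction.
* **Fat-mass equation**: FM (kg) = 42.5 − 5.73·sex − 0.02254·PA − 26.3·height
  + 0.4879·BV, sex coded 1 = female / 2 = male, PA in min/week, height in m,
  BV the calibrated volume in litres. Coefficients are arguments, so the
  model can be re-fit on new cohorts.
* **Error reporting**: percent error uses the reference mean as base and is
  reported at full precision (5.28/67.03 = 7.88%; the published rounding to
  7.8% is left to display).

## Concordance layer

Bland–Altman uses the n−1 SD, limits of agreement fixed at mean ± 1.96 SD
(not z-for-n adjusted), a t-based CI for the bias and the standard LoA-CI
formula SE = SD·√(1/n + 1.96²/(2(n−1))). Published agreement tables for this
class of system print CI half-widths ≈ 2.03·SE whose exact construction is
not identifiable; those CIs are therefore audited only through the LoA point
arithmetic, and this package always reports *signed* limits.

ICC forms: ICC(2,1) (two-way random, absolute agreement) by default, ICC(3,1)
selectable; the source software behind published values rarely names the
form, and both intra- and inter-observer uses are k-rater grids. Mean squares
are computed from explicit sums of squares and verified against an
independent `aov` decomposition to 1e-9; confidence intervals follow
Shrout–Fleiss/McGraw–Wong with a Satterthwaite approximation for ICC(2,1).

Best-subsets regression enumerates all 2^p − 1 subsets, reporting R²,
adjusted R² = 1 − (1−R²)(n−1)/(n−p−1) and Mallows' Cp = RSS_p/MSE_full − n +
2(p+1); the full model satisfies Cp = p + 1 exactly, which doubles as a
self-test.

## Reliability study emulation

`make_fixture_cohort()` emulates the validation design: n subjects, two
independent observers, three repeats each (six scans per subject).
Covariates follow cohort-like distributions (women 1.60 ± 0.07 m, 61 ± 8 kg;
men 1.72 ± 0.05 m, 78 ± 13 kg; ages 20–42; 43% sedentary), each subject's
phantom is scaled so its volume matches weight/1.05 L (a typical adult
density of 1.05 kg/L), reference BV replicates add 40 mL noise, and the
reference fat mass follows the package's own equation plus 1.2 kg noise — a
known generative rule, so recovery is checkable. Observer/repeat scans
re-jitter the camera rig (2 cm stand-off, 1 cm height/lateral; observer 2
systematically 1.5 cm further back) and apply the depth noise model; the
recorded camera poses are the jittered ones, so repeat-to-repeat variance
comes from noise, dropout and re-discretization, as in a rig that records
its own calibration.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run the full-resolution
(512 × 424, `poisson_depth` 8) pipeline on ten phantoms spanning 37–110 L
for volume recovery and calibration, and a three-subject, six-scan
reliability study; module tests use reduced image scales and `poisson_depth`
5–7 where the property under test is resolution-independent. These sizes
keep a complete run in single-digit minutes on one core while exercising
every stage at native resolution.

## Known limitations

* The lateral in-fill bias is scene-shape dependent; calibration transfers
  across phantoms of similar build (fitted error < 1%) but a calibration
  fitted on one population should not be assumed for another.
* The registration prior means genuinely miscalibrated extrinsics beyond a
  few millimetres are *not* recovered — they surface as measurement variance
  instead. This is a property of the two-view geometry, not of the solver.
* The IR model is two-level reflectance; segmentation robustness to shading,
  specularities and emissivity variation on real skin is untested here.
* Thoracic gas volume is consumed as an already-applied correction to the
  reference volume; the breathing-tube measurement is hardware-bound and out
  of scope.
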