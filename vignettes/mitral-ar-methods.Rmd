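---
title: "Methods: stereo reconstruction and scale-adaptive registration for mitral valve AR overlays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stereo reconstruction and scale-adaptive registration for mitral valve AR overlays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitralAR)
```

## The problem

During robot-assisted mitral valve repair the surgeon sees only the atrial
surface of the valve. Structures at direct risk from annular sutures — the
circumflex artery, the aortic valve cusps, and the conduction tissue in
Koch's triangle — are invisible. An augmented-reality overlay projects a
preoperative CT-derived model of exactly these structures onto the stereo
endoscopic view, after registering it to a metric 3D reconstruction of the
intraoperative scene.

Two geometric facts shape the method:

1. **The endoscope is a calibrated stereo rig.** After undistortion and
   rectification, a correspondence between the eyes at horizontal disparity
   $d$ implies depth $z = f B / d$ (focal length $f$ in pixels, baseline $B$
   in mm), so a disparity map is a metric surface reconstruction.
2. **The intraoperative annulus is smaller than the preoperative one.**
   On cardiopulmonary bypass the heart is arrested and unloaded; a rigid
   (6-DoF) registration cannot absorb this size change, so the registration
   is a 7-DoF *similarity* transform $p \mapsto s R p + t$ with an explicit
   scale $s$, observed clinically in the range 0.61–0.79.

## Pipeline

`run_case()` executes the stepwise workflow; each stage is an exported
function and a CLI subcommand (`inst/cli/mvar.R`):

| stage | function | output |
|---|---|---|
| rectification | `rectify_pair()` | row-aligned ideal pair + rectified rig |
| correspondence | `compute_disparity()` | sub-pixel disparity + validity mask |
| triangulation | `disparity_to_cloud()`, `clean_cloud()` | metric point cloud (mm) |
| initial alignment | `landmark_similarity()` | closed-form similarity from 4–8 annulus key points |
| refinement | `scale_adaptive_icp()` | converged `similarity_transform` |
| validation | `build_validation_report()` | LRE, diameter error, scale |
| presentation | `render_overlay()`, `stereo_composite()` | stereo overlay frames |

## Camera model

Both eyes are pinhole cameras with Brown–Conrady distortion (three radial,
two tangential coefficients) — the de facto standard for endoscope
calibration. Distortion inversion uses fixed-point iteration (20 iterations
or a step below 1e-10). Intrinsic calibration itself is *not* implemented:
parameters arrive in a YAML/JSON file, because calibration is performed once
preoperatively with standard tooling. Rectification resamples both eyes to a
shared ideal camera (mean intrinsics, zero distortion, identity relative
rotation) by inverse warping with bilinear interpolation; the rig convention
places the right camera center at $(B, 0, 0)$ in the left camera frame, so
the left rectified frame coincides with the left camera frame.

`reprojection_error()` pools all observation–projection pixel distances into
one mean, across both eyes. Under isotropic Gaussian pixel noise of standard
deviation $\sigma$ the expected value is the Rayleigh mean
$\sigma\sqrt{\pi/2}$, which the tests verify by simulation.

## Block matching

The correspondence core is a zero-mean normalized cross-correlation (ZNCC)
block matcher, written here rather than wrapped because no stereo matcher
exists in the package's dependency environment and the matcher *is* the
testable core of the reconstruction. Window sums use integral images, so the
cost volume is $O(W H D)$ regardless of block size. Design choices, each
configurable:

* **block_size = 9** — small enough to resolve the annulus ridge (tens of
  pixels wide at working distance), large enough for stable ZNCC statistics.
* **search_range = 64** candidate disparities starting at 0, left-referenced
  and positive toward nearer objects.
* **sub-pixel refinement** — 3-point parabola on the cost curve, clamped to
  ±0.5 px; skipped when the center correlation is already exactly 1, where
  interpolation could only wander off a perfect integer match.
* **validity gating** — a pixel survives only if (a) its local left-image
  variance exceeds `texture_threshold` (flat tissue cannot be matched), (b)
  the left→right and right→left disparities agree within
  `consistency_threshold` (the right-referenced map is recomputed from the
  same cost volume, so the check is free), and (c) its winning disparity is
  not truncated by window availability at the image border.
* **depth gating** — reconstructed points outside [20, 300] mm are dropped;
  a plausible endoscopic working range.

Statistical outlier removal (`clean_cloud()`) drops points whose mean
distance to their 8 nearest neighbors exceeds the global mean by more than 2
standard deviations. Nearest-neighbor queries here and in ICP go through a
kd-tree (RANN); the test suite cross-checks them against brute-force
distance computation.

## Registration

**Initial alignment.** `landmark_similarity()` is the closed-form
least-squares similarity fit: center both ordered landmark sets, take the
SVD of the cross-covariance, guard against reflection by flipping the sign
of the smallest singular value when $\det(UV^T) < 0$, and read the scale off
the trace ratio. It is exact on noiseless data (property-tested over random
transforms with scales in [0.3, 1.5]) and rejects collinear configurations,
where the rotation is under-determined.

**Scale-adaptive ICP.** The same closed-form fit is the inner solver of the
ICP loop: transform the source, find nearest neighbors in the target,
reject pairs farther than `reject_distance` (10 mm), re-fit, clamp the
scale to `scale_bounds` ([0.3, 1.5]), and stop when the RMS changes by less
than 1e-4 mm or after 100 iterations. The recorded RMS is evaluated on each
iteration's surviving pairs *after* its re-fit, so it is non-increasing.
Setting `scale_bounds = c(1, 1)` degenerates to classic rigid ICP, which
the tests verify recovers constructed rigid motions exactly.

**Which points enter ICP?** Two modes are exposed
(`--icp-points landmarks|dense`):

* `landmarks` (default): SICP runs on the 4–8 annulus key-point pairs.
  With correspondences this clean the loop converges in 2–3 iterations onto
  the closed-form fit. This is the default because the scaling factor and
  LRE are naturally reported per landmark set, and because key-point pairs
  are the one input whose correspondence is certain.
* `dense`: SICP registers points sampled uniformly-by-area from a preop
  structure mesh onto the reconstructed cloud. The target is first
  restricted to a band (`target_band_mm`, 5–6 mm) around the
  init-transformed source — the annulus-region gating without which a thin
  structure can slide along the dense scene surface. The recommended source
  is the `annulus_surface` patch (annulus plus nearby tissue), whose ridge
  profile makes the scale observable.

**Known limitation of dense mode.** One-directional point-to-point ICP onto
a *reconstructed* surface inherits the matcher's smoothing: the rim in the
cloud is slightly flattened relative to the model, and the fit converts
that profile mismatch into a small systematic scale underestimate (about
0.02–0.06 on phantom data). On clean geometry (mesh-sampled targets) dense
SICP recovers the scale to ~1e-3. The tests pin both behaviors; users who
need the scale to survive dense refinement on real reconstructions should
keep the landmark estimate or tighten `scale_bounds` around it.

**Basin of convergence.** The annulus is close to 180°-rotationally
symmetric about its normal. From an initialization rotated by more than
~60°, ICP can converge to the symmetric alias with a low RMS; a test
asserts this failure openly rather than hiding it. Landmark initialization
avoids the issue because commissure labels break the symmetry.

## Validation metrics

* **Landmark registration error** — RMS Euclidean distance between the
  registered preoperative and the intraoperative landmark sets, in mm.
* **Annulus diameter** — the paper-style point-cloud validation compares a
  measured intraoperative diameter with the implanted annuloplasty ring
  size. The measurement itself is not standardized, so two definitions are
  exposed and recorded in the output: maximum pairwise distance (default)
  and intercommissural distance. The error is *signed*
  (diameter − ring size); a negative median means the measured annulus is
  slightly smaller than the prosthesis.
* **Cohort statistics** — `summary_stats()` reports the median and the
  quartiles by linear interpolation at positions $(n{+}1)/4$ and
  $3(n{+}1)/4$ (`quantile(type = 6)`). This rule was fixed because it
  reproduces the published LRE interquartile range exactly from the
  per-patient values; of the published diameter-error IQR it reproduces
  only the lower bound, and no standard quartile rule we tried yields the
  published upper bound — recorded here as a discrepancy rather than
  silently absorbed.

## The synthetic phantom

Every stage is testable without clinical data through `generate_phantom()`,
which builds a ground-truthed scene a stereo endoscope could plausibly see:

* **Annulus**: a closed saddle curve
  $(a\cos\theta,\, b\sin\theta,\, h\sin 2\theta)$ with $a = 17.5$,
  $b = 13$, $h = 3$ mm — a ~35 mm long-axis diameter consistent with the
  published intraoperative diameters (30–43 mm) and the qualitative saddle
  shape of the mitral annulus.
* **Tissue surface**: the hyperbolic paraboloid $z = 2h\,(x/a)(y/b)$, which
  contains the saddle curve exactly, plus a Gaussian rim of height 2.5 mm
  and width 2.5 mm along the annulus ellipse. The rim matters: the fibrous
  annulus is a geometric ridge in vivo, and without it the reconstruction
  would carry no shape information about the structure the registration
  anchors on.
* **Texture**: seeded band-limited noise (60 random-plane sinusoids,
  wavelengths 1.5–8 mm) so block matching is well-posed; a constant texture
  is the explicit degenerate input for the validity-mask tests.
* **Landmarks**: 4–8 points sampled exactly on the annulus curve, the first
  two at the anterior and posterior commissures (the long-axis ends).
* **Preoperative model**: the scene structures mapped through the inverse
  of a known similarity transform whose scale defaults to 0.72 and is
  configurable across (0, 1.5]; preoperative landmark picks get isotropic
  Gaussian noise (default 1 mm, manual-pick level). The default rotation
  magnitude (≤ 25°) and translation (±30 mm) stand in for the arbitrary CT
  frame.
* **Rendering**: z-buffered rasterization with barycentric,
  perspective-correct interpolation and headlight Lambertian shading; the
  returned per-pixel true depth map is the oracle for reconstruction tests.
  Default rig: $f = 450$ px at 256×192, $B = 5$ mm — a wide-angle
  endoscope-like geometry in which the whole annulus fits the view at
  85 mm working distance.

What the phantom does *not* emulate: specular wet-tissue appearance,
motion/deformation, occlusion by instruments, and realistic CT segmentation
noise. Passing phantom tests therefore demonstrates the geometric and
numerical correctness of the pipeline, not clinical-grade robustness on
operating-room imagery.

## Problem sizes and determinism

The test suite runs phantoms at 160×120 with a 56×56 surface grid; the
demo case (`make_demo()`) uses 256×192 with a 96×96 grid. The 50-case
registration-recovery study samples 1500 source and 12000 target points per
case. All randomness — phantom noise, texture, sampling, subsampling — is
derived from explicit seeds, and identical config+seed re-runs produce
bit-identical artifacts (the run manifest records an MD5 per output file to
make this checkable).
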