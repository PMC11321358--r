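---
title: "Linking phrenic-nerve capture thresholds to site-to-nerve distance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking phrenic-nerve capture thresholds to site-to-nerve distance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phrenicmap)
```

## The problem

During radiofrequency ablation of atrial fibrillation, the right phrenic
nerve (RPN) runs epicardially close to the superior vena cava and the right
superior pulmonary vein, and can be injured by lesions delivered near its
course. Operators infer the nerve's position by pace-mapping: pacing from
endocardial sites at high output (up to 50 mA at 2 ms pulse width) and
watching for diaphragmatic capture, then bracketing the capture threshold by
differential pacing at 10, 20 and 30 mA. Each site therefore carries one of
five ordered labels: threshold ≤10 mA, >10–≤20 mA, >20–≤30 mA, >30–≤50 mA,
or non-capture at 50 mA.

The clinical question is geometric: *how far is a pacing site from the
nerve, given its capture-threshold category?* A reference cohort (45
patients, 1033 sites) answered it by delineating the nerve on CT, fusing the
CT with the electroanatomical map, and measuring the shortest 3D distance
from every site to the segmented nerve. Because the site-level raw data of
that cohort are not deposited, this package reproduces the analysis on two
kinds of synthetic data:

* a **calibrated cohort** drawn from truncated normal distance
  distributions whose post-truncation moments match the published
  per-category summaries — the input for reproducing the diagnostic tables;
* a **geometric scenario** that exercises the full measurement chain
  (anatomy → CT-style volume → segmentation → centerline → registration →
  distances → simulated thresholds → statistics) with known ground truth.

## The calibrated cohort generator

The published summaries give, per category, the site count and the mean, SD
and minimum of the measured distance:

```{r}
reference_category_summaries()$categories
```

For each category we model the distance as a normal distribution
left-truncated at the printed minimum and solve the truncated-normal moment
equations for the parent mean and SD. With $\alpha = (a-\mu)/\sigma$ and
hazard $\lambda(\alpha) = \phi(\alpha)/(1-\Phi(\alpha))$,

$$\mathbb{E}[X \mid X \ge a] = \mu + \sigma\lambda, \qquad
  \mathrm{Var}[X \mid X \ge a] = \sigma^2\bigl(1 - \lambda(\lambda-\alpha)\bigr),$$

and the ratio of the variance to the squared excess mean depends on
$\alpha$ alone, so a single bisection (`calibrate_truncated_normal()`)
recovers $\alpha$, then $\sigma$ and $\mu$ in closed form. Draws use the
inverse-CDF method, so every sampled distance respects the printed minimum
exactly.

Truncation is not a nicety: with untruncated normals at the printed
mean/SD, the non-capture category (19.2 ± 6.5 mm) would place a sizeable
mass below 10 mm, and the very high specificity of the non-capture cutoff
(0.976) could not be reproduced. The printed minima carry exactly the tail
information the diagnostic panel depends on, which is why the generator
treats them as hard truncation points.

Each replicate cohort draws exactly the published 74/319/135/197/308 sites
per category (1033 in total), attaches patient labels (45 patients) and the
published 872/161 left-atrial/SVC region split. Patient and region labels
mirror the reference cohort's structure only; all statistics pool sites,
as the reference analysis did. We treat the printed SDs as site-level
quantities — the reference report analyses "1033 pacing sites" without
patient weighting, and no patient-level dispersion is published.

## Diagnostic statistics

All statistics operate on site-distance records:

* **Category summaries** report computed counts, percentages, means, SDs
  (sample, $n-1$) and minima. Percentages are what the counts imply: the
  >10–≤20 mA row is 319/1033 = 30.9%. (The reference report prints 30.1%
  for that row, which is inconsistent with its own counts; we report the
  computed value and document the discrepancy in the test suite rather than
  reproduce it.)
* **Spearman correlation** between the 5-level ordinal category and the
  distance uses mid-ranks for the heavy ties and the large-sample p-value.
* **Between-category comparisons** are Welch (unequal-variance) two-sided
  t-tests; the reference analysis says only "parametric t-test", and Welch
  is the safer default for unequal group sizes and spreads. No
  multiple-testing correction is applied (none was in the reference).
* **ROC / AUC**: positives are sites with distance > 10 mm (the clinically
  motivated safety margin); the predictor is the ordinal category with
  non-capture ranked highest. The AUC is the tie-corrected rank-sum
  (Mann–Whitney) estimator — with a 5-level predictor, almost every pair is
  a tie or a comparison between tied blocks, so the tie correction is the
  substance of the estimate, not a refinement. Its confidence interval is a
  nonparametric bootstrap percentile interval over sites (2000 resamples by
  default); the reference bracket's method is unstated, so we make no claim
  of reproducing the exact interval, only the point estimate.
* **Sensitivity/specificity panel**: for each cutoff (>10, >20, >30,
  >50 mA), sensitivity is the share of remote sites (distance > 10 mm)
  whose category lies beyond the cutoff, specificity the share of close
  sites at or below it. Nesting (Se non-increasing, Sp non-decreasing in
  the cutoff) holds by construction and is asserted in the tests.

Reproduction runs aggregate 200 replicate cohorts. At that replicate count
the Monte-Carlo standard error on the aggregated proportions is about
0.001–0.002, an order of magnitude below the comparison tolerances, while a
full reproduction completes in about a second.

## The geometric scenario

`generate_anatomy()` builds a left-atrium-like ellipsoid shell (default
semi-axes 30 × 26 × 27 mm, jittered ±4% per seed — a ~4.3 cm atrium) with
four tubular PV ostia, and a nerve polyline running superior→inferior along
the right aspect of the shell, offset outward by a clearance profile that
dips to ~1.2 mm near the right-superior-PV region and grows past 30 mm away
from it — matching the reported 1 mm-to->3 cm range of endocardium-to-nerve
proximity. Pacing sites are sampled area-uniformly on mesh faces of the
septal (or SVC/RA) patch, so they lie exactly on the shell.

The CT side mimics the reference acquisition trick: the nerve path is
rasterized into a Hounsfield volume as a curved tube of diameter 5 voxels
at 900 HU over a soft-tissue background (40 HU), so a simple ≥850 HU
threshold recovers exactly the written voxels. Design choices the source
description leaves open, and how we resolved them:

* "5 pixels wide" is implemented as a 3D-isotropic tube diameter of
  `width_voxels × mean(spacing)`; whether the original marking was in-plane
  only is unknowable from the description, so the parameter is exposed.
* Distances are measured to the nerve **centerline**, not the tube surface;
  the reference does not say which it used. Centerline is the unambiguous
  choice (surface distance would subtract an arbitrary marker radius), and
  the tube radius bounds the difference.
* Voxel indices refer to voxel centers; world = origin + index · spacing;
  axis-aligned grids only — synthetic volumes never need oblique direction
  cosines.

Centerline extraction orders segmented voxels by geodesic distance through
the 26-neighbourhood voxel graph between the two automatically detected tube
tips, takes per-bin centroids along that ordering, trims half a tube radius
at each end (the hemispherical end caps would otherwise bias the endpoints),
and smooths with a running mean over one tube diameter. A purely greedy
nearest-neighbour chaining of voxel centers was rejected: it visits every
voxel of the tube cross-section and destroys the arc-length parameterisation
on curved tubes, whereas the graph-geodesic ordering is stable for the
curvature radii (≥20 mm) the anatomy produces. At 1 mm voxels the recovered
centerline stays within one voxel diagonal (√3 mm) of the generating path,
and propagated site-distance errors shrink with voxel size (≤0.5 mm at
0.25 mm voxels in the round-trip tests).

Map-to-CT fusion — unpublished in the reference, which used a custom
program — is defined here as paired-landmark Kabsch initialisation (four PV
ostium centers plus the chamber centroid as fiducials) followed by
point-to-point ICP on shell point clouds. No scale term: both frames are
metric. Correspondence is brute-force nearest neighbour, adequate at the
few-thousand-point scale and free of library dependencies. Since no
registration accuracy figure is published, the pipeline quantifies
sensitivity instead: a pure translation of k mm changes any site-to-nerve
distance by at most k mm (the distance-to-a-set function is 1-Lipschitz),
and the misregistration driver sweeps rotations and translations to show
the realised propagation is well below the bound.

## The capture model

The observed category is generated from the true distance through a
virtual-electrode model: threshold at distance $d$ and pulse width $w$ is

$$T(d, w) = \bigl(I_0 + c\,d^2\bigr)\left(1 + \frac{\tau}{w}\right),$$

a quadratic strength–distance law (the standard far-field point-source
approximation) under Weiss–Lapicque strength–duration scaling with
chronaxie $\tau = 1.5$ ms, the pulse width reported to reach the
phrenic-nerve rheobase. Observed thresholds carry multiplicative lognormal
noise (thresholds are positive; dispersion grows with magnitude), and
boundary values land in the lower-labelled category, matching the "≤"
labels of the protocol.

The reference study fits no such model — this module exists so the geometric
scenario produces a realistic threshold–distance overlap rather than a
deterministic staircase. `calibrate_capture_params()` fits the distance
coefficient, the noise SD and (by default) the rheobase by multi-start
Nelder–Mead so that pushing the cohort's distance mixture through the model
reproduces the published per-category mean distances; with the rheobase
free the fit lands within 1.5 mm on every category mean, which the
two-parameter fit cannot quite achieve. Common random numbers across
objective evaluations keep the search surface smooth. With calibrated
parameters the geometric scenario's AUC falls in the 0.81–0.84 range across
seeds, consistent with the reference value of 0.846 and far from the
near-perfect separation a noise-free model would give.

Only the 4-level differential protocol is simulated; finer
operator-discretion threshold refinement is not modelled, since its
prevalence in the reference cohort is unknown.

## What the synthetic data do and do not show

Passing tests demonstrate that the *measurement and analysis chain* is
correct (geometry against brute-force oracles, registration against known
motions, rasterization round trips against generating paths) and that the
*statistical reproduction* follows from the published summaries plus the
truncated-normal assumption. They do not validate the truncated-normal shape
itself against patient data, nor real CT delineation of a nerve, nor
deformable anatomy, cardiac motion, or vendor map export — all replaced by
ground-truth synthetic constructs. The geometric anatomy randomises only
global scale and the closest-approach position, not true inter-patient
morphological variability.

## Numerical conventions

Millimetres everywhere; readers convert on load. Ties in polyline distance
break to the lowest segment index; `which.min` conventions make every
reported argmin deterministic. Degenerate inputs are rejected loudly
(zero-length segments, collinear Kabsch landmarks, disconnected voxel sets,
single-class ROC input) or flagged (single-voxel centerline, undefined
SD/correlation). Seeds: every stochastic stage derives its seed from the run
seed via `stage_seed()` (a linear counter scheme below 2^31), so stages can
be rerun independently and whole pipelines are bit-reproducible; RNG state
is saved and restored around seeded internals, so seeded calls do not
disturb the caller's stream.

## Problem sizes used in the shipped analyses

Calibrated reproduction: 200 cohorts × 1033 sites. Geometric scenario:
415 sites (350 septal + 65 SVC/RA, the published 872/161 mix scaled down),
1 mm voxels over a ~75 × 80 × 100 mm volume, 60-vertex nerve path, 500-point
ICP clouds. Oracle suites: ~1000 random geometry instances, 100-seed Kabsch
noise studies, 10-seed calibration recoveries. These sizes were chosen so
the whole suite runs comfortably on a laptop while keeping Monte-Carlo error
well inside every comparison tolerance.
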