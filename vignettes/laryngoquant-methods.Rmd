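---
title: "laryngoquant: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{laryngoquant: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic phantoms emulate, and the decisions taken where the method
description left the design open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The problem

Laryngopharyngeal reflux (LPR) irritates the laryngeal mucosa; clinically
this shows as reddening of the vocal cords and hue/texture changes around
the arytenoid cartilage. Endoscopic grading is subjective, and the
alternative (24-hour pH monitoring) is invasive. The pipeline here
quantifies the visual signs directly from endoscopic frames: pick a sharp
frame, normalize its brightness, segment the anatomy, extract hue and
texture features, and classify.

The pipeline assumes the frame shows a roughly *en face* larynx: a dark
glottis near the image center shaped like an inverted triangle, bright
columnar vocal cords flanking it, a bright roughly rectangular arytenoid
region in the upper part of the image, and an intensity valley between each
cord and the false vocal cord lateral to it. All structure rules and scan
directions encode exactly this geometry; frames violating it are expected
to fail segmentation loudly (classed `lq_not_found` conditions), not
silently.

## Frame screening and selection

Non-throat frames are filtered by the mean red chromatic fraction
$\overline{R/(R+G+B)}$ with threshold 0.4. The chromatic fraction (rather
than a raw channel mean) was chosen because it is illumination-robust and
naturally lies in $[0,1]$, matching the stated 0.4 cutoff; the method
description does not define "red component" precisely. Mucosa scores
roughly 0.45 on the phantoms, gray/blue non-throat content about 0.25–0.33.

Blurred frames are removed by a *single-pass* filter: the mean gray-level
variance of the surviving frames is computed once and frames strictly below
it are dropped. Iterating this filter to a fixed point would eventually
discard everything but the single most-textured frame, which is not the
intent; the single pass is documented behavior, and `screen()` is
idempotent only in the sense that a second pass over its output recomputes
a new mean.

Four focus scores are provided (gray images are the BT.601 luma plane,
another undocumented choice made here): population variance,
sum-modulus-difference over all in-bounds adjacent pairs, the Sobel
gradient-magnitude sum, and the Laplacian energy with kernel
$[0\,1\,0;\,1\,{-4}\,1;\,0\,1\,0]$. Sobel and Laplacian responses are
summed over *interior* pixels only — no padding — because border
extrapolation would let frame edges dominate the score. SMD is the default
selection score, as in the source method (cheapest with adequate
precision). Ties select the lowest frame index.

## Brightness compensation

Frames are shifted in luma so their mean Y equals 125:
$I(x,y) = O(x,y) + (S - O_m)$ on the Y plane of the *full-range* BT.601
transform. Full range (Y in $[0,255]$, no studio swing) is required for the
printed means (103.72, 125, 158) to be interpretable. Chroma planes are
untouched, so every hue feature is invariant to the compensation by
construction. Out-of-range luma is clipped to $[0,255]$ and the clipped
fraction is attached to the result and warned about; when nothing clips the
post-shift mean equals the target up to coefficient rounding (the
acceptance script verifies 125 ± 0.5 and observes agreement at ~1e-8).

## Segmentation

**Glottis.** The darkest structure. The "lower bound of the threshold" is
implemented as $TH = \mu - \sigma$ of the global gray histogram: the method
description never defines it, but the printed pair ($\mu = 158$,
$TH = 131$) implies $\sigma \approx 27$, consistent with one population
standard deviation below the mean. Components below $TH$ are filtered by
structure rules — minimum area 0.5% of the image, centroid within the
central 50% of both axes, bounding-box width/height at most 2 (the glottis
is tall, so wide "east–west" regions are rejected) — and the largest
survivor wins. None of these three constants is stated in the source; they
are the package's defaults, exposed in `structure_rules()`.

**Arytenoid cartilage.** Bright binarization at $\mu + 0.5\sigma$, one pass
of 3×3 erosion, largest component, then rules (centroid in the upper 40% of
rows; aspect at least 1, rejecting tall "south–north" regions). The
candidate is refined by a contracting snake initialized on the convex hull
of the 2-pass-dilated candidate. The 3×3 square structuring element and the
1/2 erosion/dilation pass counts are package choices; the source names the
operations but not the element.

**Vocal cords.** The glottis is dilated (3×3, two passes) and transected by
the horizontal line through its centroid. On each side the smoothed gray
profile (moving average, width 3) is scanned outward: the first maximum is
the cord ridge, the minimum beyond it is the valley between cord and false
cord. A valley must sit at least 20 gray levels below the ridge —
otherwise the side fails with `lq_not_found`; without this prominence
requirement flat noise always produces a spurious "valley". The cord's
outer edge is localized at the half-prominence crossing of the
ridge-to-valley descent (where the region is slit).

The cord region is then *grown*: a thin five-column strip centered between
the glottis edge and the slit line, spanning the glottis rows, is inflated
by an active contour until the cord edges stop it (next section). The
final cord masks have the glottis subtracted, enforcing disjointness, and
left/right are assigned by centroid column in image space (patient
laterality is out of scope).

## The active-contour model

The snake minimizes
$E = \int_0^1 \tfrac12\big(\alpha |v_s|^2 + \beta |v_{ss}|^2\big)
      - |\nabla I|^2 + E_{con}\, ds$
discretized over $n$ control points with cyclic finite differences.
Optimization is greedy neighborhood descent (Williams–Shah style): each
point in turn moves to the position in its $(2r+1)^2$ neighborhood that
minimizes its exact local contribution to the total energy. Because the
local contribution contains every term of the objective that depends on the
point, the total energy is non-increasing per iteration by construction —
the property the test suite asserts — and, with ties keeping the current
position and strict improvements resolved to the lowest row-major
candidate, evolution is fully deterministic. This scheme was chosen over
Euler–Lagrange gradient descent because it is robust, integer-friendly and
matches the iteration-count framing of the adaptive stopping rule; the
stationarity conditions of the continuous formulation are what the greedy
scheme approximates at convergence.

The image is smoothed with a Gaussian (σ = 1 px) *before* the gradient is
squared, widening the capture range of edges relative to speckle.

**Direction of evolution.** The internal elasticity makes a bare snake
contract. The arytenoid snake therefore starts *outside* its target (on the
dilated candidate hull) and contracts. The cord snake must *grow* — the
source describes the cord range "growing" toward the gap at the false cord
— which is implemented as a pressure (balloon) term folded into the
constraint energy: $E_{con} = \gamma \cdot \text{area}$ with orientation
normalized so $\gamma < 0$ inflates. The default cord pressure is
$\gamma = -40$: large enough to dominate speckle fluctuations of the
smoothed squared gradient (tens of units), small enough that the per-step
pressure gain (≈ γ × point spacing ≈ 80–100) cannot climb out of a genuine
edge trench (several hundred units deep on the phantoms).

Two further choices proved necessary and are deliberate deviations from the
initially sketched design:

* **Bending stiffness of the cord snake is β = 10** (the generic snake
  default stays α = 1, β = 0.5). With β = 0.5 the inflated contour, once
  balanced against the cord edges, keeps sliding tangentially into the
  deepest gradient spots, folds, and its enclosed area decays — measured on
  the default phantom as a DSC drop from 0.91 to 0.68 between iterations 22
  and 41. β = 10 freezes the converged contour without noticeably rounding
  the cord corners.
* **Growth is confined by a constraint box**: $E_{con}$ is 0 inside
  [glottis row extent] × [glottis edge, slit line] and large (1e4) outside.
  Without it the contour's corner lobes grow indefinitely into featureless
  background, where no image edge can balance the pressure term. The box
  is anatomy the pipeline has already measured, not a tuned constant.

**Entropy-difference stopping.** The number of cord iterations cannot be
fixed: cord size varies with lens distance and left/right cords differ, so
a fixed count over- or under-segments. After each iteration $i$ the
Shannon entropy $H_i$ (base 2, 256-bin histogram) of the *range grown by
that iteration* — the symmetric difference between the regions enclosed
before and after — is recorded, and the stopping iteration is
$n^\ast = \arg\min_{i \in [13, 41]} |H_i - H_{i-1}|$, ties to the smallest
$i$. While the contour grows through tissue each ring carries that
tissue's entropy (≈ 5 bits on phantom speckle); once the contour freezes
the rings are empty, entropy drops to exactly 0 and successive differences
collapse, so the argmin lands at or just after convergence. The
alternative reading — entropy of the *cumulative* enclosed region — was
implemented first and found fragile: the cumulative entropy drifts so
slowly during homogeneous growth that chance near-zero differences stop
the contour mid-growth (observed on 3 of 20 phantom seeds). The iteration
bounds 13 and 41 are the published ones. A contour whose enclosed region
empties before iteration 13 raises `lq_degenerate_contour`.

## Features

36 features per image, named as in the published inventory (`A_*` for the
arytenoid, `VC_* max/min` over the two cords, `VC/A_*` ratios):

* **Hue**: mean R, G, B; HSV hue H in degrees, averaged *circularly*
  (vector mean of angles) to avoid the 0°/360° wrap; Cb and Cr from the
  full-range BT.601 transform (achromatic = 128). The cord/arytenoid ratio
  uses the mean of the two cord means over the arytenoid mean — the source
  says "ratio of the vocal cords to arytenoid cartilage" without fixing
  max/min/mean. For H this is a ratio of angles and is only meaningful
  while the arytenoid hue stays away from 0°, which holds for
  mucosa-colored regions; the caveat is documented rather than papered
  over.
* **Texture**: symmetric, normalized GLCM at angle 0°, displacement 1,
  8 quantization levels over $[0,255]$ (the level count is not stated in
  the source; 8 keeps matrices well-populated for regions of a few
  thousand pixels). Statistics: energy $\sum p_{ij}^2 \in [0,1]$
  (1 iff the region is constant), contrast
  $\sum (i-j)^2 p_{ij} \in [0,(k-1)^2]$, correlation with marginal
  moments (defined 0 when a marginal variance vanishes), and homogeneity
  as the inverse difference $\sum p_{ij}/(1+|i-j|)$ — the source names
  homogeneity but never defines it. All four are validated against a
  brute-force pair-enumeration oracle in the tests.

Feature ranking uses the standard two-class Fisher criterion
$f = (\mu_1-\mu_2)^2/(\sigma_1^2+\sigma_2^2)$ (the source names the
discriminant without a formula; this form reproduces the scale of the
published scores, 0.0019–0.6568). $f$ is affine-invariant, 0 for identical
class distributions, and guarded for zero-variance degenerate input. The
published feature table contains two apparent typos — "VC_cor max" listed
twice and a homogeneity min exceeding its max — the canonical name list
here uses each max/min pair once and makes no attempt to reassign the
printed values.

## Classification

**LPR detection.** Soft-margin SVM with RBF kernel. Neither kernel nor
hyperparameters are given in the source; defaults are C = 1 and bandwidth
σ = median pairwise distance of the standardized training features, both
configurable. The solver is a small sequential-minimal-optimization (SMO)
implementation written for this package (no SVM library ships with the
supported environment); it uses Platt's second-choice heuristic with a
deterministic fallback chain instead of random working-set selection, so
training is reproducible without a seed. Cross-validation is a seeded
shuffled 10-fold split on the 1:1 balanced cohort, with standardization
statistics taken from the training folds only. **The positive class is
non-LPR** — the clinical study defines it that way — so "sensitivity" is
the non-LPR detection rate and the false positive rate counts LPR samples
called non-LPR. The inversion is deliberate and flagged in the function
documentation.

**Severity grading.** RSI bins 13–20 / 21–30 / 31–45 (scores below the
inclusion rule of 13 are rejected as out of range; the bins partition
[13, 45] with no gaps, asserted exhaustively in the tests). The grader is
a fully connected 5-4-3 network, sigmoid throughout, one-hot targets,
batch gradient descent on the mean squared error with the published
hyperparameters: 1000 cycles, learning rate 0.65, momentum 0.5. Weights
initialize uniformly in $[-0.5, 0.5]$ from a configured seed; inputs are
standardized with training statistics (the source is silent on scaling).
The description conflicts with itself on whether RSI is also an input
("five features and RSI" vs "five processing units"); this implementation
uses 5 inputs and RSI-derived class labels. The output layer size, never
stated, is 3 — one unit per grade. Stratified 10-fold CV assigns folds
per class round-robin after a seeded shuffle; classes smaller than the
fold count simply appear in fewer folds (the severe class has 14 samples
in the published mix).

## The phantom generator

`make_phantom()` renders the anatomy the segmentation relies on: a filled
inverted-triangle glottis (vertices parameterized; the source only states
the shape), cord and arytenoid rectangles, valley strips, mucosa
background, plus seeded Gaussian luminance speckle (sd 7 in the bright
structures — needed so GLCM features are non-degenerate), per-channel
Gaussian noise (sd 6), optional Gaussian defocus and an additive
illumination offset. The LPR effect — +25 on cord R, ∓12 on arytenoid
Cb/Cr, ×1.6 cord speckle contrast — is applied before noise. The default
frame is 256×256 (no pixel dimensions are published; geometry scales with
the requested size). RSI scores follow the inclusion rule: non-LPR in
[0, 12], LPR in [13, 45] with a 38/54/14 mix over the severity bins.

`make_feature_cohort()` bypasses rendering and draws the 36 features as
unit normals with class-mean shifts *only* on the five selected features;
the default shifts are calibrated a priori as $\delta = \sqrt{2f}$ from
the published Fisher scores, so the synthetic cohort reproduces the
published separation scale rather than an arbitrary one.
`make_severity_cohort()` places the three grades 4 sd apart along the unit
diagonal of the five features — "well separated" fixed before any test was
run. All generators are bitwise deterministic per seed.

**What a green test establishes — and what it does not.** The phantoms
prove the pipeline's mechanics: that each stage implements its stated
contract, that segmentation recovers known geometry through noise and
blur, that the adaptive stopping lands after convergence, and that the
classifiers recover planted effects at the published effect scale. They do
not establish clinical performance: phantom structures are rectilinear
with sharp edges, speckle is stationary Gaussian rather than mucosal
texture, there is no specular reflection, motion artifact, occlusion or
anatomical variation, and the published headline numbers (DSC 0.85–0.93,
97.16% detection accuracy, 96.48% severity accuracy) are properties of a
clinical dataset this package cannot access. The synthetic DSC figures
landing in the published range says the method is implemented coherently,
not that it generalizes.

## Numerical conventions

* Images are numeric arrays `(rows, cols, 3)` in $[0, 255]$; masks are
  logical matrices; all indexing is 1-based `(row, col)` (the R
  convention — interface descriptions elsewhere may count from 0).
* Snake coordinates are `(x = col, y = row)` at 1-based pixel centers;
  enclosed regions use even-odd scanline polygon fill.
* Greedy moves require an energy improvement of at least 1e-9; GLCM
  statistics reject matrices whose entries deviate from sum 1 by more
  than 1e-6; dice of two empty masks is 1; red fraction of a black pixel
  is 0.
* Left/right symmetry is exact, not approximate: separable convolutions
  sum mirrored shift pairs as `(left + right) + center`, profile smoothing
  does the same, and the cord initialization is built outward from the
  glottis, so mirroring the input image yields bitwise-mirrored masks with
  left/right swapped. The test suite asserts `identical()`, not a
  tolerance.
* Sharpness-score and stack indices are 1-based; `make_frame_stack()`
  reports the sharp frame's index accordingly.

## Known limitations

* Segmentation assumes one glottis, two cords and one arytenoid block in
  the canonical arrangement; multiple candidate regions are resolved by
  the structure rules and largest-area tie-break only.
* The cord snake's constraint box depends on the measured valley; if the
  false-cord valley is absent or below the 20-gray-level prominence the
  side fails rather than guessing.
* The SMO solver targets cohorts of a few hundred samples (kernel matrix
  in memory); it is not intended for large-scale training.
* JPEG input requires the suggested `jpeg` package; TIFF is unsupported.
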