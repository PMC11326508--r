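---
title: "Vertebra landmark detection and Cobb angle estimation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertebra landmark detection and Cobb angle estimation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinemark)
```

## The problem

Scoliosis severity is graded by the Cobb angle: the angle between the
endplates of the two most-tilted vertebrae in a spinal curve on an
anterior–posterior (AP) radiograph. Automated pipelines estimate it from 68
landmarks — the four corners of each of the 17 annotated thoracic and lumbar
vertebral bodies. `spinemark` implements the computational core of a
keypoint-detection approach to this task: the ground-truth encodings a
detection network is trained against, the composite loss, the decoding of
network outputs back to landmarks, the Cobb measurement, and the evaluation
metrics — together with a parametric spine simulator so the whole chain is
testable without clinical images.

## Coordinate conventions

Images use the standard raster frame: origin at the top-left pixel, `x`
along columns, `y` along rows increasing downward, 0-based, real-valued.
Corners are indexed 1 = top-left, 2 = top-right, 3 = bottom-left,
4 = bottom-right, so corners {1,3} trace the left vertebral boundary, {2,4}
the right, and the bottom corners {3,4} of one vertebra face the top corners
{1,2} of the next. These groupings are what the line interpolation and the
adjacent-vertebra offsets rely on.

## Dual-coordinate ground-truth encoding

Supervision lives on a grid downsampled by `k` (default 4). Six targets are
encoded per image:

* **Centre heatmap** — an unnormalized 2-D Gaussian disc
  $\exp(-d^2 / 2\sigma^2)$ with peak 1 at each quantized vertebra centre;
  overlapping discs merge by element-wise maximum. The disc radius follows
  the detection-style overlap rule: the largest shift of the vertebra's
  bounding box that keeps IoU ≥ 0.7 with itself, with $\sigma = r/3$; a
  fixed-$\sigma$ override exists. The radius rule keeps the spatial
  tolerance proportional to vertebra size.
* **Centre offset** — the fractional part $(x/k - \lfloor x/k \rfloor,\,
  y/k - \lfloor y/k \rfloor)$ stored at the quantized centre cell, so
  decoding restores centres exactly; quantization would otherwise cost up
  to $k\sqrt2/2$ px.
* **Polar corners** — each corner as $(r, \theta)$ about its centre, with
  $x = x_{ct} + r\cos\theta$, $y = y_{ct} + r\sin\theta$ in the y-down
  frame and $\theta \in (-\pi, \pi]$ from the two-argument arctangent.
  Near-symmetric vertebral bodies make the four radii similar, which is the
  motivation for regressing corners polar-relative rather than in absolute
  Cartesian coordinates.
* **CPIE** (centre point interval estimator) — at the centre cell of
  vertebra $i \le 16$, the full-resolution vector to centre $i+1$. The 16
  intervals telescope: centre 1 plus their sum reproduces centre 17.
* **AVIE** (adjacent vertebra interval estimator) — at the centre cell of
  vertebra $i \ge 2$, the four-vector from the bottom corners (3,4) of
  vertebra $i-1$ to the top corners (1,2) of vertebra $i$. Both interval
  targets inject inter-vertebral structure, which matters most in the
  cluttered lower spine.
* **Vertebral lines** — see below.

Interval vectors are anchored at the upper vertebra's cell for CPIE and the
lower vertebra's for AVIE, matching the direction each quantity is measured
in; the anchoring choice is a convention, and radii are kept in
full-resolution pixels so the encode–decode round trip is exact to
floating-point precision (verified to 1e-6 px over 200 random spines in the
tests).

Decoding applies 3×3 non-maximum suppression (a cell survives iff it equals
its neighbourhood maximum; ties all survive), then either fixed top-k
(k = 17, ties broken by value then row-major index) or adaptive
thresholding (every survivor strictly above 0.05), restores sub-pixel
offsets, rescales by `k`, sorts by `y`, and reads the polar corner field at
each surviving cell. Network outputs are clamped to the target ranges at
decode time (offsets to [0,1), radii to ≥ 0); encoded targets are already
in range, so this only affects imperfect predictions.

## Sparse-to-dense vertebral line interpolation

The 17 centres (middle line) or 34 left/right corners are interpolated by a
chord-length-parameterized cubic spline passing through every control point,
and the curve is resampled at 100 arc-length-equidistant points including
both endpoints. Arc length is computed on a dense piecewise-linear
subdivision (10,000 segments) and inverted by interpolation — simpler than
ODE integration and accurate well below the 1% equidistance tolerance the
tests enforce (a quarter circle resamples to within 0.005% of the analytic
spacing). The dense 100-point line is a drop-in auxiliary regression target
that converts sparse landmark supervision into a description of overall
spine morphology. The default uses only the middle line: the corner lines
zigzag (vertebral side edges are not collinear with each other), and in
practice the middle line carries nearly all of the signal at a third of the
parameters.

Design notes: chord-length parameterization and endpoint inclusion are
conventions chosen here (the alternative — excluding endpoints — shifts all
samples by half a spacing and nothing else); degree 1 (polyline) is
available for ablations.

## The composite loss

$$L = \alpha_1 L_{hm} + \alpha_2 L_{center} + \alpha_3 L_{corner}
    + \alpha_4 L_{CPIE} + \alpha_5 L_{AVIE} + \alpha_6 L_{VIL},$$

with $\alpha_{1..5} = 1$ and $\alpha_6 = 0.05$, keeping the six terms on a
similar scale (the line term sums over 100 dense points). $L_{hm}$ is the
penalty-reduced focal loss of the keypoint-heatmap lineage
($\alpha = 2$, $\beta = 4$, normalized by the number of peak cells); all
offset terms are masked L1 over supervised cells only; the corner term uses
wrapped angular differences $\min(|\Delta\theta|, 2\pi - |\Delta\theta|)$
on the $\theta$ channels, since plain L1 would spike spuriously at the
$\pm\pi$ branch cut; $L_{VIL} = L_{vil,l} + L_{vil,m} + L_{vil,r}$ with
disabled lines contributing zero. All losses are pure functions on
grids/masks, testable without a network.

## The reference network

A U-shaped encoder–decoder with stride-2 3×3 convolution encoder blocks,
nearest-upsample decoder blocks with additive skip connections, a shared
3×3 head convolution, 1×1 convolution heads for the five grid pathways
(heatmap through a sigmoid), and a vertebral-line head that global-average-
pools the bottleneck into a fully connected layer emitting normalized line
coordinates in [0,1]. Forward and backward passes are written directly in R
(im2col convolutions, hand-derived gradients — verified against numeric
differentiation in the tests) with an Adam optimizer; this keeps the
package self-contained on a CPU-only stack.

Two presets share the machinery. The `"toy"` preset (4+2 blocks, widths
8–32, ~33k parameters, 192×64 inputs, two normalized coordinate channels
appended to the input to ease sub-pixel regression at this scale, Adam at
1e-3) exists to demonstrate the end-to-end learning signal: it overfits two
simulated cases to under 10% of the initial loss in 500 steps on one CPU
core (about a minute), after which decoded landmarks recover the ground
truth to under 4 px at toy resolution. The `"resnet34"` preset reproduces
the 5+3-block layout, 1024×512 geometry and Adam 1.25e-4 of a full-scale
detector; training it to clinical performance requires a real dataset and
GPU-scale compute and is outside this package's scope.

## Cobb angle measurement

Per vertebra, the slope vector runs from the left-edge midpoint (corners
1,3) to the right-edge midpoint (corners 2,4). The 17×17 angle matrix is
the arccosine of normalized slope dot products (cosines clipped to [0,1],
capping pairs at 90°); the main thoracic angle MT is the global maximum,
attained between an upper vertebra $p_1$ and lower $p_2$. For a C-shaped
spine, PT is the angle between vertebra 1 and $p_1$, TL between vertebra 17
and $p_2$. An S-shaped spine is detected by a sign test: the lateral
displacement of the 34 endplate midpoints relative to the first-to-last
chord; if it changes sign, the secondary angles are instead regional maxima
(above $p_1$ and below $p_2$ when the main bow sits in the upper image
half; both from the region above otherwise). This regional rule
reconstructs the AASCE-style reference measurement; it sits behind
`s_curve_rule = TRUE` so the plain C-shaped rule can be forced. Parallel
endplates give zero; the measurement is invariant to global translation,
rigid rotation and uniform scaling (tested to 1e-9 degrees).

## Evaluation metrics

* **MDE** — mean Euclidean distance over index-aligned landmarks, in
  pixels; reportable on the upper ten / lower seven vertebra split that
  tracks the background-interference gradient, and pooled over all
  landmarks of a dataset.
* **SMAPE** — per case, summed absolute PT/MT/TL errors over summed
  (pred + gt), case-averaged, ×100 (percent scale); per-angle variants use
  one angle. Symmetric under pred↔gt by construction. A case whose
  denominator vanishes is an error rather than silently dropped.
* **Self-adaptive MDE** — decode centres adaptively (threshold 0.05, so
  the detection count may differ from 17), decode corners per centre, match
  predicted to ground-truth vertebrae by minimum-total-distance assignment
  (Hungarian algorithm on centre-to-centre Euclidean costs; rectangular
  instances leave surplus predictions unmatched), then average landmark
  error over matched vertebrae only (4 landmarks per pair). This separates
  localization error from vertebra-ordering error: a pure index swap has
  positive MDE but zero self-adaptive MDE. Matching on centres (rather
  than whole landmark sets) is the cheaper of two defensible costs; the
  assignment itself is solved exactly (verified against factorial brute
  force for n ≤ 7).

## The simulator and what it does (not) show

`spine_sim_params()` draws a centerline $x(t) = W/2 + \sum_k A_k
\sin(2\pi f_k t + \phi_k)$ with $y$ linear in $t$, places 17 vertebrae at
equal arc spacing, and rotates each body to the local tangent. Defaults —
1024×512 canvas, a 40 px main bow plus 12 px secondary bow (each seed
jitters amplitudes 50–100%, frequencies ±10% and phases), body sizes
growing 64→100 × 36→50 px down the spine, gap fraction 0.25 — produce
realistic S-shaped geometries with Cobb angles roughly 10–45°. Tangent
angles are closed-form, so each case carries analytic true Cobb angles
computed through the same regional partition as the estimator; landmark-based
estimates recover them to well under 1° over 100 seeds. Rendering fills the
quadrilaterals brightly over a dark background, blurs edges, adds Gaussian
noise, and ramps positive clutter texture from zero at the top row to its
maximum at the bottom — emulating the heavier soft-tissue interference of
the lower AP radiograph.

What passing these tests shows: the encodings are exactly invertible, the
losses and metrics implement their formulas, the partition rule is
self-consistent, and the architecture can fit its targets. What they do not
show: performance on real radiographs — the simulator has no ribs, pelvis,
exposure variation, anatomical shape variation beyond rectangles, or
annotation noise, and the toy network is an overfitting probe, not a
detector.

## Numerical choices and limitations

* Problem sizes in the default suite: 200 spines for round-trip fidelity,
  100 for Cobb recovery and Hungarian cross-checks, 150 for file round
  trips, 30 for equidistance; the toy run is 500 steps on 2 cases.
* Ties: NMS keeps all equal maxima; top-k breaks ties by value then
  row-major index; the adaptive threshold comparison is strict (`> 0.05`).
* Degenerate inputs: a zero-length slope vector (collapsed vertebra) is an
  error in the Cobb measurement; a corner coincident with its centre
  encodes as $(r, \theta) = (0, 0)$; an empty prediction set is an error in
  matching; an empty mask gives a zero masked loss.
* The MAT reader supports the minimal uncompressed v5 subset used by
  AASCE-style annotation arrays (a single 68×2 double matrix), not general
  MAT files.
* The S-curve secondary-angle partition is a reconstruction of the
  reference behaviour from its published description; since the simulator's
  analytic truth flows through the same partition, parameter-recovery tests
  validate the landmark pipeline rather than the partition choice itself.
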