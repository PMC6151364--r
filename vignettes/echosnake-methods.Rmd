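---
title: "Coarse-to-fine left-ventricle segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine left-ventricle segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(echosnake)
```

## The problem

Quantifying left-ventricle (LV) function from three-dimensional
echocardiography (3DE) — cavity volumes at end-diastole and end-systole, and
the ejection fraction derived from them — requires segmenting the LV blood
pool in volumes with low signal-to-noise ratio, strong speckle texture, and a
left atrium (LA) that borders the LV across the mitral orifice with virtually
identical blood-pool intensity. That last property is the classic failure
mode of deformable-surface segmentation in the ventricle: with nothing but
image forces, a surface fitted to the LV can extend through the valve plane
into the atrium ("boundary leak").

`echosnake` implements a coarse-to-fine pipeline for this problem:

1. **Coarse stage** — a small fusion fully-convolutional network (FCN)
   labels each 2D short-axis slice of the volume as LV / background,
   trained with a class-balanced weighted cross-entropy loss.
2. **Geometric initialization** — the stack of coarse per-slice masks is
   converted to a surface: per-slice foreground centroids, a quadratic
   center-curve correction along the long axis, an 8-ray average radius per
   slice under a circular cross-section assumption, equal-interval contour
   resampling, and reconstruction of a stacked-ring *tube mesh* closed at
   the apex and open at the base.
3. **Fine stage** — a 3D snake (active surface) evolves the tube mesh by
   gradient descent on an energy combining internal smoothness, an
   image-derived edge attraction, and a *spatial regularization* term
   `eta * |X - X_init|^2` that anchors the surface to its initialization —
   the package's mechanism against LV-to-LA leak.
4. **Evaluation** — mean and Hausdorff surface distances, the modified Dice
   dissimilarity `D* = 1 - 2|V ∩ V_t| / (|V| + |V_t|)`, cavity volumes and
   ejection fraction, Bland-Altman agreement, and the pixel metrics
   (accuracy, mean accuracy, mean IOU) for the coarse stage.

Because public 3DE volumes with ground truth cannot be redistributed here,
the package ships a **synthetic phantom generator** that makes every stage
testable end-to-end, with analytic ground truth.

## The phantom and what it does (not) emulate

`phantom_spec()` describes a digital phantom: a dark half-ellipsoid LV
cavity (semi-axes `a = b = 16`, `c = 40` mm by default, truncated at its
equatorial/basal plane — the standard geometric LV approximation, consistent
with the circular-cross-section assumption the initializer makes), a bright
myocardial shell (4 mm), a darker tissue background, and optionally an
atrial cavity of the same blood-pool intensity beyond the basal wall,
connected to the LV through a circular mitral opening — reproducing the
geometry that causes boundary leak. Texture is first-order only:
multiplicative unit-mean gamma speckle (relative standard deviation 0.15 by
default, chosen so the cavity/wall intensity histogram stays bimodal) and an
isotropic 1 mm Gaussian blur. All randomness flows from one integer seed;
identical spec + seed is bit-identical.

What the phantom does **not** emulate: sector/cone acquisition geometry,
depth-dependent attenuation and resolution, anisotropic point-spread,
papillary muscles, trabeculation, or temporal coherence. Tests passing on
the phantom therefore demonstrate *algorithmic correctness* (geometry
recovery, energy minimization, metric arithmetic, leak containment under the
stated hazard), not clinical-grade accuracy on real ultrasound.

`degrade_mask()` turns the analytic mask into a plausible *coarse network
output* — per-slice morphological boundary jitter, hole dropout, spurious
off-target islands — so the initializer and snake can be exercised without
training (the pipeline's `mode = "degraded-truth"`).

## The coarse network

The segmenter is a configurable-width reimplementation of the feature-fusion
FCN topology: a VGG-style encoder of `depth` pooling stages, and one *skip
stream* per enabled pooling stage. Each stream reduces its feature map to
the two class channels with a 1x1 score convolution, passes it through a
**residual module** — four 3x3 convolutional layers of two kernels each,
every layer followed by batch normalization and ReLU, wrapped by an identity
shortcut — and returns to full resolution through learnable two-channel
transposed convolutions (kernel 4, stride 2, one per pooling level). The
streams are summed into the final two-class score map. The two deepest
streams are always present (the baseline fusion); adding shallower streams
injects low-level features. Where the residual module's "two kernels" per
layer could mean two convolutions or two output channels, we adopt two
output channels: it keeps the identity shortcut shape-consistent after the
score convolution has already reduced the stream to `n_classes = 2`
channels, matching the architecture's overall 21-to-2 channel-reduction
logic.

**Loss.** With `Y+` foreground and `Y-` background pixels in a slice's
ground truth and `a = Y- / (Y+ + Y-)`,

```
loss = -a * sum_fg log P(y=1) - (1 - a) * sum_bg log P(y=0),
```

which up-weights the rare LV class. Probabilities are clamped at `1e-12`
before the log (the expression is undefined at `P = 0`), so a confidently
wrong pixel contributes a large finite penalty, never `NaN`. For a balanced
mask (`a = 0.5`) the loss is exactly half the unweighted cross-entropy —
one of the property tests.

**Training** is SGD with momentum in two stages: during stage 1 the encoder
("backbone") is frozen bit-exactly and only the skip streams train; stage 2
fine-tunes everything. The learning rate decreases linearly in steps of
`decay_every` iterations, `lr(t) = lr0 * (1 - t_dec / max_iter)`; the
step-wise reading of "linear decrease every N iterations" was chosen over a
continuous ramp because a per-iteration ramp makes `decay_every` meaningless.
Reference defaults are `lr0 = 1e-4`, momentum 0.99, batch 256, 10000
iterations with `stage1_iter = 1000`.

**Desk-scale choices.** The engine is pure R (im2col + BLAS matrix
multiplication with hand-written backpropagation), sized for the package's
study conditions: 200 phantom slices of 64 x 64, `base_width = 8`,
`depth = 3`, batch 8, 300 iterations, momentum 0.9, gradient-norm clipping,
and — after training — a batch-norm *recalibration pass* that replaces the
small-batch running statistics with statistics aggregated over 16 fresh
training batches. Recalibration matters: with batch 8 the running means lag
the trained network and cost roughly 0.2 mean IOU at inference. This toy
run trains in a few minutes on one CPU and reaches mean IOU above 0.8 on
its training slices; transfer learning from natural-image weights is
replaced by a name-and-shape weight-loading hook
(`load_pretrained_weights()`), keeping the package free of external
artifacts.

## The initializer

Per slice, the raw LV center is the mean of all coarse foreground pixels.
Raw centroids are noisy — spurious islands shift them, and small apical
cross-sections are easily corrupted — so `x(z)` and `y(z)` are each fitted
with a quadratic polynomial in the slice index and evaluated everywhere,
including across empty interior slices. The pipeline weights this least
squares fit by per-slice foreground area: small (apical) slices carry the
least reliable centroids, and the basal end of an unweighted fit has enough
leverage to be dragged millimetres off-axis by a single corrupted apical
slice. `fit_center_curve(weights = NULL)` remains the plain unweighted fit.

Radii assume a circular cross-section: eight rays at 45-degree increments
are cast from the corrected center (correction precedes scale estimation, in
pipeline order), each measuring the distance to the outermost
foreground/background transition of the slice's main connected component —
islands are ignored because coarse masks contain them and component
selection is otherwise unspecified. Rays that see no foreground are
excluded; a slice with fewer than four valid rays is rejected. `R` is the
mean of the valid rays, and the contour is resampled as `n_points = 36`
equally spaced points on the circle of radius `R` (10-degree sampling; the
contour point density is a package choice, configurable).

Contours are kept at 0-based positions `0, k, 2k, ...` (`k = 10` by
default); the basal-most contour is force-included so the mesh spans the
full chamber regardless of the remainder. Rings are stitched band by band
(matching points by angular index), the apical end is capped by a triangle
fan to an apex vertex placed one slice beyond the apical ring *on the
fitted center curve*, and the base stays open. The resulting tube mesh is a
2-manifold topological disc (Euler characteristic 1) with consistent
winding — both are unit-tested. Apex/base orientation is auto-detected from
the foreground-area gradient along z (the cross-section shrinks toward the
apex) and can be overridden.

## The snake

The surface `X` evolves to minimize

```
E = sum( 1/2 alpha |X'|^2  +  1/2 beta |X''|^2
         + delta E_ext(X)  +  eta |X - X_init|^2 )
```

with reference weights `alpha = 0.1, beta = 0.2, delta = 0.1, eta = 0.1`.
The conventional 1/2 is applied to both internal terms. Design choices that
the energy's one-parameter notation leaves open:

- **External energy.** `E_ext = -|grad(G_sigma * I)|^2`, the canonical
  edge-attraction energy of the snake literature, computed spacing-aware
  (anisotropic voxels respected) and normalized to `[-1, 0]` so `delta` is
  independent of the intensity scale. Energies and forces at vertex
  positions come from trilinear interpolation, and the force is the *exact
  derivative of the interpolant* — sampled energies and reported gradients
  agree to machine precision inside a voxel cell, which makes the
  finite-difference gradient check in the test suite meaningful.
- **Discretization.** The parametric derivatives are realized on the tube
  mesh as circular finite differences along each ring plus chain differences
  along each vertical (angular-index) chain, the apex terminating every
  chain. Differences are **arc-length weighted** (rest lengths measured on
  the initialization mesh and held fixed, so the internal energy stays an
  exact quadratic form): after resampling with `k = 10` the vertical ring
  gap is about five times the in-ring point spacing, and unweighted
  differences would make axial tension dominate and crush the tube along
  its long axis.
- **Descent.** Explicit Euler, `X <- X - tau * grad E`, `tau = 0.1` mm per
  unit force, with *energy backtracking*: a step that would increase the
  total energy is retried with halved `tau`. This guards against the
  explicit-scheme stability limit — degenerate near-apex rings with tiny
  rest lengths can otherwise blow the mesh to the volume boundary — and
  incidentally guarantees the monotone-energy property the tests assert.
  Convergence is declared when the mean vertex displacement falls below
  `tol = 1e-3` mm; `max_iters = 500` caps a run. Vertices leaving the
  volume are clamped to its boundary and counted.
- **Base handling.** Vertices move in full 3D (it is a 3D snake). The open
  basal ring is *not* frozen to its plane by default: the spatial anchor
  (`2 eta (X - X_init)` restoring force) is what stabilizes the base
  axially, and freezing the ring's z coordinate would make the leak
  phenomenon structurally impossible to study. `fix_base_plane = TRUE`
  restores the frozen-base variant.

**What the regularizer does — and what leak looks like here.** With
`eta = 0.1`, the anchor force `0.2 * d` mm^-1 exceeds the normalized edge
force (at most `delta * |grad E_ext| ~ 0.05`) once a vertex strays ~0.25 mm
from its initialization: the snake is a *local refiner* of the coarse
result, which is precisely the stated role of spatial regularization — and
on the atrium-enabled phantom the regularized surface finishes with zero
vertices beyond the basal plane and a strictly smaller Hausdorff distance
than the unregularized run (both are acceptance checks). A genuinely
*advancing* leak under `eta = 0`, however, does not occur with this model
class: a pure edge-attraction snake exerts no force inside homogeneous
blood pool, and at the open basal rim the net force points away from the
edge end, so the unanchored surface *retracts and deforms* (its Hausdorff
distance grows by 1 mm or more) rather than marching into the atrium.
Advancing leak requires either a leaky initialization (a coarse stage that
already includes LA, which the anchor would then preserve) or
pressure/balloon forces, which are out of scope. The capability experiments
that need large deformations (hemisphere recovery from a 0.8x-scaled
initialization) therefore run with the anchor off (`eta = 0`, `delta = 1`,
`sigma_ext = 1.5` mm on the noiseless phantom); with `eta` at its default
those runs would — by design — stay at their initialization.

## Metrics

- `d_m` is implemented exactly as printed in the benchmark definition: the
  **sum** of the two directed mean nearest-point distances (most literature
  averages them; `averaged = TRUE` toggles that convention).
- `d_h` is the standard symmetric Hausdorff distance (the benchmark's
  printed formula is typographically garbled; if the 95th-percentile
  variant was intended, values would differ).
- Surfaces are compared point-set to point-set after area-weighted random
  resampling of the meshes (default 5000 points, fixed seed), with a
  chunked exact nearest-neighbor scan; an O(n^2) brute-force oracle backs
  the tests.
- `D*`, volumes (voxel count x voxel volume / 1000 -> ml), EF
  `(EDV - ESV)/EDV`, Bland-Altman bias / sd / 1.96-sd limits, and the
  two-class pixel metrics follow the standard definitions; truth-absent
  classes are excluded from the means with a warning. A tube mesh can be
  rasterized back to a voxel mask (`voxelize_tube_mesh()`, chain-wise
  z-interpolation + even-odd polygon fill) so surface and voxel metrics can
  be compared on the same object.
- The "modified correlation" statistic that sometimes accompanies these
  benchmarks is never defined precisely enough to reimplement and is
  deliberately omitted.

## Reproducibility and problem sizes

Every stochastic stage (speckle, degradation, initialization of weights,
batch order, surface resampling) draws from one integer seed; the pipeline
writes every artifact with an MD5 manifest and is bit-reproducible for a
fixed configuration and seed in single-threaded BLAS mode. The problem
sizes used throughout — 64 x 64 x 80 voxel phantoms at 1 mm spacing, 200
training slices, 300 training iterations, 36-point rings, 5000-point
surface samples — are the package's study conditions, chosen to keep a
full run in the minutes range on a single CPU while leaving every claimed
property measurable.

## Known limitations

- The phantom's realism gap (above) bounds what green tests imply about
  clinical data.
- The circular cross-section assumption biases radii on strongly elliptical
  chambers; the initializer reports per-ray radii so the residual
  anisotropy is visible.
- The snake's edge-based external energy has a capture range of a few
  `sigma_ext`; initializations further than that from the true boundary
  converge slowly or not at all (hence the anchor-off capability settings).
- `d_m`'s summed convention is twice the averaged convention; comparisons
  across software must normalize conventions first.
- The pure-R network engine is adequate for the toy study conditions only;
  it is not a general-purpose deep-learning stack.
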