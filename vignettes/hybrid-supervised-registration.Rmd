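---
title: "Hybrid-supervised deformable registration: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid-supervised deformable registration: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridreg)
```

## The registration problem

Intersubject registration of brain CT aligns the head anatomy of one
patient (the *moving* image $M$) to that of another (the *reference* $I$),
so that regional labels — for instance a middle-cerebral-artery supply
territory used in stroke scoring — can be transported between subjects.
Two obstacles make this hard for learning-based methods: dense
ground-truth deformation fields between real subjects do not exist (manual
annotation of per-voxel correspondence is infeasible), and anatomical
differences between individuals can be large.

`hybridreg` addresses both with *hybrid supervision*. A deformation-field
simulator draws random multiscale affine + elastic displacement fields
$F_g$ and warps a real image $M$ into a synthetic reference
$I^0 = M \circ (\mathrm{id} + F_g)$. By construction $F_g$ is the exact
gold standard for registering $M$ to $I^0$, so a supervised loss on the
predicted field is available without any manual annotation. In parallel, a
second, *self-supervised* pair — $M$ with a different real subject $I^1$ —
is scored purely by image similarity, anchoring the network to real
intersubject variation.

## Model

A convolutional encoder–decoder maps the channel-concatenated pair
(moving, reference) to a dense displacement field $u$ under the backward
warping convention: the warped image reads the source at $x + u(x)$ (voxel
units; mm statements convert per axis through the voxel spacing). The
encoder halves resolution per level by max pooling; the decoder upsamples
and fuses the matching encoder features by channel concatenation; every
block carries one 3×3 convolution per configured dilation rate, expanding
the receptive field without extra parameters. The final 1×1 projection is
initialized near zero (weight sd $10^{-5}$, zero bias) so the untrained
network predicts a near-identity transform — early optimization then
starts from the identity rather than from a random, violently deforming
map.

The training loss is

$$L = \alpha\, L_F + \beta\, L_{M0} + \gamma\, L_{M1},
\qquad \alpha = \tfrac{1}{13},\ \beta = \gamma = 0.4,$$

with

* $L_F = \frac{1}{|\Omega|} \sum_{p} \lVert F_p(p) - F_g(p) \rVert_2$, the
  mean Euclidean deviation between predicted and gold fields, computed on
  mm-converted vectors so that anisotropic spacings (e.g.
  $0.36 \times 0.36 \times 2$ mm) weight the axes physically;
* $L_{M0}, L_{M1}$: the negative mean *squared* windowed normalized
  cross-correlation between each reference and its warped prediction.
  Windows are $(2r+1)$-wide per axis (default half-width $r = 4$),
  border-clamped, with an $\varepsilon = 10^{-5}$ denominator guard so
  constant windows (stripped background) contribute ≈ 0 rather than being
  excluded or dividing by zero.

The squared NCC is insensitive to the sign and to affine intensity maps of
either image, which suits z-scored CT. Both similarity terms and the warp
itself are differentiated analytically; the package implements the full
backward pass (convolution, pooling, upsampling, trilinear warp, windowed
NCC) in compiled code and optimizes with Adam
($\beta_1 = 0.9, \beta_2 = 0.999, \epsilon = 10^{-8}$).

## Training protocol

Each step draws a moving subject and a distinct reference uniformly from
the cohort, manufactures the supervised pair with a fresh simulator draw,
adds Gaussian noise (sd 0.05 on z-scored intensities) to all network
inputs (losses keep the clean targets), forwards both pairs through the
same weights, and takes one Adam update on the combined gradient — batch
size is fixed at 1 pair + 1 pair. "Until convergence" is operationalized
as a fixed step budget plus best-checkpoint selection on validation
landmark endpoint error; validation pairs are preconstructed once per run
so their gold vectors stay fixed. Three further measures damp the noise
inherent to batch-size-1 optimization: the learning rate follows a linear
warmup (first 5% of steps) and cosine decay to 5% of its peak; gradients
are clipped to a global norm of 0.3 (roughly the median unclipped norm,
so typical steps pass untouched while spikes from the similarity terms at
large misalignment are capped — without it, runs intermittently stall in
poor basins); and the weights used for validation and returned by the fit
are a Polyak (exponential moving) average of the optimization trajectory
(`ema_decay = 0.99` by default).

## The simulator

Deformations compose an affine map (uniformly drawn rotation, scale,
shear, translation about the grid center) with a multiscale elastic field:
i.i.d. Gaussian displacements on coarse control grids (spacings 8, 16, 32
voxels), linearly upsampled, Gaussian-smoothed (σ = 2 voxels) and summed,
then rescaled so the maximum vector magnitude equals the configured mm cap
exactly. Composition places the elastic field outermost:
$u(x) = a(x) + e(x + a(x))$. Two regimes model the spread of intersubject
deformation: a small regime (rotation ±10°, scale 0.9–1.1, shear ±0.05,
translation ±10 mm, elastic ≤ 5 mm) and a large one (±20°, 0.8–1.25,
±20 mm, ≤ 15 mm), drawn with probability 0.8/0.2. The source material
quantifies neither the parameter distributions nor the "appropriate
proportion" of large deformations; these values are this package's own
calibration — plausible for intersubject head alignment — and every one is
config-exposed. On single-slice (2D) grids, out-of-plane motion is
suppressed: only the in-plane rotation, shear and translation act and the
z-component of the elastic field is zero.

## Phantoms: what they emulate, and what they do not

Clinical head-CT cohorts with territory annotations are generally private,
so the package ships a phantom generator that every other module can be
exercised against. A phantom is an ellipsoidal head: a bone shell
(1000 HU) around a brain compartment (35 HU), paired CSF-filled
ventricles (8 HU), air background (−1000 HU), Gaussian HU noise (sd 4 —
all plausible nonenhanced-CT values, chosen here since the source
material gives none), plus a vascular-territory label shaped as a radial
shell sector of the brain and deterministic feature landmarks (ventricular
horn tips, inner-skull midpoints pulled strictly inside the brain). Since
landmarks are defined by the constructed geometry, their correspondence is
exact both across subjects and under any known deformation — the synthetic
stand-in for manually annotated structural points.

`generate_subject()` jitters the geometry (radii, ventricle placement,
territory sector, head position) by offsets proportional to
`variation_scale`, emulating intersubject anatomical variation;
`variation_scale = 0` reduces to the deterministic phantom. The default
desk-scale grid is 64×64×16 voxels at (1, 1, 2) mm; a `"paper"` preset
mirrors a clinical raster (512×512×64 at 0.36×0.36×2 mm) but is not used
by the tests.

Phantoms deliberately omit sulcal/gyral texture, bone inhomogeneity,
pathology, and scanner artifacts. Passing tests on phantoms therefore
demonstrates that the machinery — simulator supervision, losses,
optimization, evaluation — works end to end and that the network can
recover the simulator's deformation family on skull-stripped, z-scored
images; it does not certify clinical-grade accuracy on real CT.

## Preprocessing

Skull stripping thresholds bone at 300 HU, closes the shell
morphologically (radius 1 voxel, 6-connectivity) and takes the largest
connected component of non-bone tissue not reachable from the grid border
— i.e. the cavity enclosed by the shell. The source material names the
step but not an algorithm; this construction targets phantoms and clean
CT, not BET-grade clinical stripping. A volume with tissue but no bone is
treated as already stripped, which makes the operation idempotent.
Z-scoring uses mean and *population* sd over brain-mask voxels only
(background would otherwise dominate the statistics); outside the mask the
output is 0.

## Numerical choices

* **Interpolation and boundaries.** All image sampling is trilinear (or
  nearest for masks/labels) with border clamp; replicate-edge was chosen
  over zero fill to avoid dark halos entering the similarity windows.
  Landmark transport never clamps — out-of-extent points are flagged and
  excluded, and reported alongside the metric.
* **Composition vs. sequential warping.** `compose_fields()` reproduces
  sequential warping up to interpolation error in the interior; at the
  border the composite cannot reproduce the double clamping of
  intermediate coordinates, so consistency checks compare interior voxels.
* **Windows on singleton axes.** Similarity windows shrink to the axis
  (radius `min(r, n-1)`), so single-slice grids get genuine 2D windows.
* **NMI.** Joint histograms use 32 equal-width bins per image over its own
  range and the normalization $2 I(A;B)/(H(A)+H(B))$, which is bounded in
  [0, 1] and equals 1 for identical non-constant images. Constant images
  raise an error (zero entropy) rather than returning a conventional
  value.
* **Aggregates.** Cohort reports use the sample sd (n−1), the usual
  "mean ± sd" table convention.
* **Determinism.** Every random draw flows through one explicit, seedable
  stream (`hr_rng`); the global RNG state of the session is saved and
  restored around each draw. Fixed (config, seed) reproduce training
  histories and evaluation reports bit-for-bit (runtimes excluded).

## Desk-scale problem sizes and defaults

The package's reference experiments (tests and the acceptance script) run
a deliberately scaled-down protocol chosen to exercise the full method on
a single CPU: 2D phantom cohorts of 14 subjects (8 train / 2 val / 4
test) on 64×64 grids with `variation_scale` 0.3, the default network
(4 levels, dilation rates 1 and 2), 2000 training steps, and evaluation
over 8 simulated test pairs. Two training defaults were set empirically at
this scale, where the step budget is small: learning rate $10^{-3}$
(at $10^{-4}$ the near-zero-initialized output layer cannot reach the
±10–20-voxel displacement range within the budget) and dropout
$p = 0.05$ (heavier dropout visibly slows convergence at this capacity;
the option remains for larger runs). The paper-scale 3D configuration
(512×512×64) exists as a preset but is not exercised by the tests.

## Known limitations

* No diffeomorphism or inverse-consistency guarantees: fields are free
  displacements, and no smoothness penalty beyond the simulator's own
  construction is imposed (the training loss defines none).
* The simulator's parameter distributions are a stand-in for — not an
  estimate of — real intersubject deformation statistics.
* The NCC window size, learning-rate schedule and architecture details
  (depths, widths, dilation rates, dropout placement) are not specified by
  the source material; the defaults here are this package's own choices,
  all config-exposed.
* Runtime columns in evaluation reports are hardware-dependent and
  excluded from reproducibility guarantees.
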