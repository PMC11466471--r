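---
title: "Limited-angle non-coplanar CBCT: simulation, GAN reconstruction and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Limited-angle non-coplanar CBCT: simulation, GAN reconstruction and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noncopcbct)
```

## The problem

In non-coplanar radiotherapy the treatment couch is rotated away from 0°,
which lets beams reach targets (typically intracranial) from directions a
coplanar plan cannot. The price is imaging: with the couch rotated, the
gantry-mounted kV imager can only sweep a restricted arc before colliding
with the couch or patient, so a cone-beam CT (CBCT) acquired in that
position is severely limited-angle and not reconstructable by conventional
filtered back-projection. Without volumetric imaging at the treatment couch
angle, the rigid setup error (three translations, three rotations) cannot
be verified in the position actually treated.

This package implements a reconstruction-by-synthesis approach: a
generative adversarial network (GAN) whose generator receives (a) the
coplanar CBCT of the same subject — a prior that fixes the anatomy — and
(b) the limited-angle non-coplanar projection stack, which carries the
information about the current pose, and outputs the non-coplanar CBCT
volume. One model is trained per couch angle. Everything runs on synthetic
digital head phantoms, so the full pipeline — simulate, train, reconstruct,
evaluate — is reproducible from code with no external data.

## Acquisition model

A `cone_beam_geometry()` fixes the source-to-isocenter distance (1000 mm),
source-to-detector distance (1500 mm), a flat 1024 × 768 detector with
0.388 mm pixels, and 0.4° per projection frame — the parameters of a
TrueBeam-class onboard imager. Desk-scale work uses smaller detectors; the
geometry is fully configurable.

The gantry arc available at each couch angle is tabulated in
`couch_arc()`:

| couch angle | arc | frames at 0.4°/frame |
|---|---|---|
| +45° | 180°–330° | 375 |
| −45° | 330°–120° (wraps) | 375 |
| +90° | 250°–310° | 150 |
| −90° | 30°–120° | 225 |

`projection_angles()` uses the half-open convention `[start, end)` — the
end angle is excluded. This is the only convention that reproduces all four
tabulated frame counts simultaneously (closed arcs would give 376/376/151/226).

Projections are digitally reconstructed radiographs (DRRs): line integrals
`∫ μ dl` of the attenuation obtained from HU by
`μ = μ_water (1 + HU/1000)`, clamped at zero, with `μ_water = 0.02 mm⁻¹`
(an effective value near 100 kVp; the beam spectrum is not modelled, and
DRRs are kept in the log/line-integral domain — the network consumes
attenuation structure, not photon counts). Rays are integrated by the
midpoint rule with step `0.5 · min(voxel spacing)` and trilinear
interpolation. On phantoms with one-voxel linear-ramp (anti-aliased)
boundaries, central-ray integrals agree with closed-form chord lengths to
about 0.03%, comfortably inside the 0.5% band we test; halving the step
changes slab integrals by far less than 0.5%.

Conventions chosen where the underlying description is ambiguous (and kept
fixed throughout): the stated "source-to-skin distance 1000 mm" is read as
the standard source-to-axis distance; the gantry rotates counter-clockwise
(viewed from +z) in the plane orthogonal to the couch-rotated patient axis,
with the source at `iso + SAD·(cos θ, sin θ, 0)`; the detector is flat and
centred on the source–isocenter ray.

## Synthetic phantoms and setup errors

`make_phantom()` builds a digital head: an ellipsoidal bony shell
(~1200 HU) around brain-like soft tissue (~40 HU with optional Gaussian
texture), spherical air cavities (−1000 HU) standing in for sinuses, on an
air background. The outer semi-axes default to (0.68, 0.86, 0.78) of the
grid half-extent — a head-like anisotropy that makes all three rotations
identifiable from shape alone, which real heads provide and a sphere would
not. Phantoms are deterministic per seed. What they deliberately do *not*
emulate: realistic CT noise spectra, bone-density gradients, streak or
scatter artifacts, and deformable anatomy (swallowing/breathing); passing
tests on these phantoms therefore demonstrates the machinery (geometry,
losses, optimization, metrics), not clinical-grade image quality.

Setup errors follow the clinical protocol: each of the six rigid parameters
is drawn uniformly — translations on ±10 mm, rotations on ±3° — then
snapped to a 0.1 mm / 0.1° grid, the resolution of couch corrections. Every
parameter is sampled each draw (a parameter is zero only by landing on
zero). Rigid transforms use intrinsic x→y→z Euler rotations about the
isocenter, rotation before translation, everywhere in the package.

`rotate_couch()` rotates about the room-vertical axis through the
isocenter — the anterior–posterior (y) axis of a head-first-supine grid.
A training sample is assembled as: ground truth = setup-error-moved,
couch-rotated coplanar prior; projections = DRRs ray-cast from that ground
truth over the couch angle's arc. `plan_dataset()` enumerates
subjects × couch angles × repeats (with per-sample seeds split from one
root seed) without generating images; `build_dataset()` materializes it.
The 80/20 train/test split is done at the subject level, never the sample
level.

## The joint loss

The generator objective is

$$L \;=\; L_{GAN} + \lambda_1 L_{L1} + \lambda_2 L_{rigid},
\qquad \lambda_1 = 100,\ \lambda_2 = 0.1 .$$

* **Adversarial term.** A patch discriminator (five 3×3×3 conv+BN+pReLU
  stages and a sigmoid-terminated fully connected layer) scores random
  cubic patches; the generator uses the non-saturating form
  `−log D(G(·))` (the literal minimax form is available behind
  `saturating = TRUE`).
* **L1 term.** Mean absolute voxel difference to the ground truth. Means —
  not sums — are used throughout so the default weights do not depend on
  grid size.
* **Rigid-bone term.** The novelty: prior and reconstruction are compared
  through a chain `moments(edge(bone(·)))` that is invariant to rigid
  motion but sensitive to shape change of the skull, because between prior
  and reconstruction there *is* a large legitimate rigid motion (the couch
  rotation plus the setup error) while the bone itself must not deform.

The bone extraction is a sigmoid `σ(scale · (I′ − t′))` with threshold
1000 HU and steepness 100000 — differentiable, unlike a hard threshold. The
steepness is applied on intensities normalized to [0, 1] over the fixed
window [−1000, 2000] HU (transition width ≈ 0.1 HU: numerically still a
step, but with usable gradients); a raw-HU mode exists for literal
fidelity. Edges come from separable 3×3×3 Sobel kernels with replicate
padding and an ε-stabilized magnitude (`ε = 10⁻⁸`) so the map stays
differentiable at zero gradient.

The moment function returns a k-vector (k = 4): element *j* is the
order-*j* *radial* central moment `Σ w‖x−c‖ʲ / Σ w` about the mass
centroid *c*. Radial moments are the standard construction that is both
translation- and rotation-invariant *and* yields one scalar per order;
per-axis central moments are not rotation-invariant and were rejected.
For a uniform ball of radius R the orders obey `m_j = 3Rʲ/(j+3)`, which the
tests verify within 2% on a 128³ grid. Inside the loss, radial distances
are expressed in units of the grid's physical half-diagonal: raw mm makes
order-4 moments of a head ~10⁶–10⁸ and the 0.1 weighting meaningless,
while dimensionless moments are O(1) and grid-size independent (a "mm"
mode keeps the literal units). The loss is the L2 norm of the
moment-vector difference, computed per whole volume.

All loss gradients — sigmoid, Sobel (via the exact adjoint of the padded
convolution), moments (including the centroid's dependence on the weights),
and the full network backpropagation — are analytic and verified against
central finite differences at relative error below 10⁻³.

Measured on the default 32³ phantom, the loss under rigid motions within
the setup-error range stays below ~6% of the reference moment norm while a
10% skull dilation exceeds 40%; the tests pin the separating tolerance τ at
10% of the reference norm.

## Networks

The generator has two encoders (coplanar volume; projection stack
resampled to a fixed angles × rows × cols grid — default 16³ at desk scale,
32×48×48 at larger scale — since the arc frame count varies by couch
angle), each with four convolutional blocks and two fully connected layers,
and a decoder with one fully connected layer and four deconvolutional
blocks, closed by a linear 3×3×3 convolution to one channel. Each
convolutional block is two 3×3×3 conv+BN+pReLU layers and a 2×2×2
max-pooling; each deconvolutional block is a 2×2×2-stride transposed
convolution followed by two conv+BN+pReLU layers. Spatial dims must be
divisible by 2⁴.

Two described reductions — stride-2 convolutions *and* max-pooling per
block — would shrink 4 blocks by 2¹² per axis, impossible at practical
sizes; the default keeps stride-1 convolutions (one clean 2× reduction per
block) and a `conv_stride = 2` variant retains the aggressive form. The
two encoder branches do not share weights; fusion is concatenation of the
two FC outputs. Batch normalization operates per sample over spatial
positions (batch size is 1 throughout), which also makes inference
deterministic. Intensities are normalized from the [−1000, 2000] HU window
to [−1, 1] and inverted on output; projection line integrals are mapped
from ≈[0, 6] to [−1, 1].

The whole stack — conv/transposed-conv via im2col/col2im kernels, BN,
pReLU, max-pool, dense, Adam — is implemented in the package with explicit
forward/backward passes, sized so the identical code runs desk-scale
(16³, ~5×10⁵ parameters, sub-second steps) and larger.

## Training and evaluation

Training alternates one discriminator and one generator Adam step per
sample. The learning rate starts at 0.002 and decays 30% per epoch
(`lr = 0.002 · 0.7ᵉ`); training halts when the monitored validation MSE
varies by less than 5% for more than three consecutive epochs (strict
inequality; a single 5% change resets the run). The monitored quantity is
volume-domain MSE by default; a DRR-domain monitor (re-cast projections vs
input projections) implements the alternative reading of "MSE between
synthetic DRR and DRR". One generator step per discriminator step; Adam
defaults; separate G/D learning-rate multipliers are exposed but not tuned.
Checkpoints carry weights, optimizer states, configs and the RNG state, so
resuming reproduces an uninterrupted run bit-for-bit.

Evaluation metrics:

* `rmse()` — root of the mean squared HU difference (the mean and root are
  part of the definition even where abbreviated elsewhere; HU-scale results
  are only consistent with that reading), whole-grid by default with an
  optional mask.
* `rigid_register()` — internal multi-resolution (4×/2×/1×) rigid
  registration minimizing mean-squared intensity difference with
  Nelder–Mead (restarted once per level) and a centroid-based translation
  init. It optimizes the fixed→moving transform — so the observed image is
  never interpolated twice — and returns the inverse. On synthetic ground
  truth this recovers injected setup errors to well under 0.1 mm / 0.1°;
  the tests require mean error < 0.3 mm / 0.3° over 20 trials.
* `overall_registration_error()` — ε, the mean Euclidean displacement of
  lat–long grid points (5° separation, plus both poles: 2522 points) on a
  30 mm sphere under the residual transform. Lat–long sampling is used
  because the construction is specified by angular separation; the
  resulting pole oversampling is a property of the fixed grid, and the
  point count is pinned by tests. Pure translations give exactly ‖t‖;
  small rotations match the per-point chord formula `2r sin(a/2) sinθ`.
  The registration direction is reconstruction→ground-truth; for the
  sub-degree motions involved the inverse direction differs negligibly.
* `bone_ssim()` — SSIM on hard-thresholded (≥1000 HU) volumes with
  standard constants (`C1=(0.01L)²`, `C2=(0.03L)²`, `L = 3000` HU — the
  intensity window width), Gaussian 11³ window by default, uniform window
  for oracle comparisons.

## Numerical choices and degenerate inputs

Trilinear interpolation everywhere, with −1000 HU (air) fill for regions
transformed in from outside the grid; out-of-grid rays contribute zero.
Radial moments guard r = 0 with a 10⁻¹² floor in the gradient; an
all-below-threshold bone mask raises an error rather than returning
moments of nothing; GAN probabilities are clamped at 10⁻⁷ before logs.
Identity transforms short-circuit resampling so `apply_rigid(v, identity)`
is exact. All randomness flows from explicit seeds: phantom texture,
setup-error draws (one splittable seed per sample), weight init, patch
sampling and shuffling.

## Problem sizes used by the tests

The suite runs phantoms at 16³–32³ (128³ only for the moment/ball check),
detectors of 10–16 columns for analytic oracles, 20 registration-recovery
trials, and a 200-step single-sample adversarial overfit at 16³ — sizes
chosen so the full pipeline, including training, exercises every code path
in minutes on one CPU core. The same code paths scale to clinical grids by
changing configuration only.

## Known limitations

Phantom realism is deliberately minimal (see above). The reconstruction
quality reachable at desk scale says nothing quantitative about clinical
data — the package validates the *machinery* against analytic and
synthetic ground truth. FDK reconstruction of the coplanar scan is out of
scope (the coplanar CBCT is an input), as are scatter, beam hardening,
detector noise, DICOM ingestion, and a single model covering arbitrary
couch angles (one checkpoint per couch angle, enforced at reconstruct
time).
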