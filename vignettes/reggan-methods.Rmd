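---
title: "Registration-guided adversarial CBCT-to-sCT translation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registration-guided adversarial CBCT-to-sCT translation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cone-beam CT (CBCT) acquired at the treatment machine guides patient
positioning in radiotherapy, but shading, streaking and lung-HU
distortion make it unreliable for quantitative use: contours are hard to
draw and dose calculated on CBCT HU is biased. Adaptive radiotherapy for
thoracic targets would benefit greatly from a CBCT whose HU can be
trusted. `regganct` implements an image-to-image translation approach:
a generator network G turns each axial CBCT slice into a synthetic-CT
(sCT) slice, a discriminator D pushes the output toward the planning-CT
appearance, and — the key idea — a registration network R absorbs the
spatial misalignment between a patient's CBCT and planning CT, so that
*unregistered* same-patient pairs can supervise the training (RegGAN).
The misaligned planning CT is treated as a noisy label whose noise is a
displacement field; R estimates that field per pair and the generator is
penalized through the *warped* output, not the raw one.

## Objective

For a CBCT slice $x$ and the (misaligned) planning-CT slice $y$:

* correction loss: $L_{corr} = \| \mathrm{warp}(G(x),\, R(G(x), y)) - y \|_1$
  (pixel mean);
* smoothness loss: $L_{smooth} = \sum_{c,\,a} \widehat{\mathbb{E}}
  \left[ (\Delta_a f_c)^2 \right]$, the mean squared forward difference
  of each field component along each axis — a spatially constant field
  costs 0, a unit ramp costs 1 per component/axis;
* adversarial loss in least-squares form: D is trained toward 1 on real
  and 0 on generated slices (patch-wise N x N score map); G toward 1.

The joint objective for G and R is
$L = \lambda_{adv} L_{adv} + \lambda_{smooth} L_{smooth} +
\lambda_{corr} L_{corr}$ with default weights $(1, 10, 20)$.
The exact functional forms (L1 correction, squared-gradient smoothness,
least-squares adversarial) are the package's choice — they are the
standard forms for this architecture family — and each sits behind its
own exported function (`correction_loss()`, `smooth_loss()`,
`adversarial_loss()`) so alternates can be swapped.

## Architecture and training recipe

* G: 7x7 convolution, two stride-2 downsampling blocks, nine residual
  blocks, two stride-2 transposed-convolution upsampling blocks, 7x7
  convolution, tanh output; instance normalization throughout. Output
  and input live in $[-1, 1]$.
* D: four stride-2 convolutions mapping a slice to an N x N patch-score
  map (N = H/16), leaky-ReLU activations.
* R: a small U-net over the channel concatenation of $G(x)$ and $y$,
  emitting a 2-component displacement field in voxel units; its last
  layer is zero-initialized so training starts at the identity
  deformation, which stabilizes the correction term early.
* Warping: bilinear with border clamping, differentiable in both image
  and field (`warp()`).
* Optimization: Adam with betas (0.5, 0.999), batch size 1, weight
  decay 1e-4 folded into the gradient; per iteration the discriminator
  is stepped once, then G and R jointly once, gradients for both taken
  against the same network state. Slice order is reshuffled every
  epoch under the run seed; everything is deterministic given the seed.
* Channel widths are configuration, not architecture. At clinical scale
  the conventional width (64) applies; the phantom-scale defaults in
  `default_config()` (generator 24, discriminator and registration
  network 16) train in a few minutes at 64 x 64 on one CPU.

The clinical recipe (learning rate 1e-4, 50 epochs over hundreds of
thousands of slice iterations) does not transfer to a 640-iteration
phantom run: at that budget a randomly initialized generator barely
moves at 1e-4. Three desk-scale adaptations are therefore available in
`train_config()` and enabled in `default_config()`; all are standard
technique and none alters the joint objective or the per-iteration
update scheme:

* a higher learning rate (2e-3 at phantom scale);
* a registration-network warm-up: before joint training, R is fitted
  for a fraction of an epoch on the raw (CBCT, CT) slice pairs with the
  same correction + smoothness objective. A cold-started R emits the
  identity field, so early correction gradients compare the generator
  against a *misaligned* label; with >600k iterations this start-up
  transient is irrelevant, with 640 it occupies a large share of
  training. Warming R up makes the correction gradients spatially
  sensible from the first joint iteration;
* an exponential moving average over the generator's weights
  (decay 0.99), used for inference. Adversarial training with batch
  size 1 leaves iteration-scale oscillation in the generator; weight
  averaging removes that noise without touching the training dynamics.

Epochs (5), patient counts (8 train / 2 test) and grid (16 x 64 x 64 at
4 mm) are fixed study conditions of the phantom experiment.

Inference is 2.5D: each axial slice is clip-normalized, translated, and
denormalized, and the slices are stacked (`translate_volume()`); no
inter-slice overlap or smoothing is applied, so any through-plane
inconsistency of the 2D model is visible rather than hidden.

## Preprocessing

HU is clipped to [-1000, 2000] (so extreme bone cannot dominate) and
mapped linearly onto [-1, 1]; the constants (midpoint 500, half-range
1500) are forced by that window. `crop_resize()` is center-anchored and
pads with -1000 HU (air, the clip floor). Rigid registration (planning
CT onto the CBCT grid, 3 translations + 3 rotations) maximizes mutual
information by default, since CBCT and CT intensities are related but
not identical; it is initialized from the body centers of mass plus a
coarse rotation sweep and refined derivative-free over a two-level
pyramid. Rigid pre-alignment matters for training too, not just for
bookkeeping: it removes the translational component of the inter-scan
misalignment, leaving the registration network only the residual
deformation to absorb.
The deformable stage that produces the evaluation reference (dCT) is a
multiresolution cubic B-spline field (two levels, coarse-to-fine
control spacing) optimized with L-BFGS-B. Its data term is mean squared
intensity difference with analytic gradients rather than mutual
information: on CBCT/CT pairs the residual intensity relation after
clipping is close to identity, and the analytic-gradient SSD objective
converges in seconds at phantom scale where a histogram-based MI
gradient would cost far more implementation surface for no measurable
benefit here. The choice is visible in the API and can be revisited.

## The synthetic phantom

`make_phantom()` builds a parametric thoracic slab: an elliptic body,
two lung ellipsoids near -900 HU, a heart sphere, esophagus and spinal
cord tubes, a vertebral block, and an esophageal tumor (CTV) whose
isotropic expansion is the PTV. Geometry is analytic so generation is
fully seeded and desk-scale; a per-patient jitter of centers and sizes
(±4 mm, ±6 %) emulates anatomical variation. Organs may be truncated by
the superior/inferior faces of the slab, as in a real thoracic field of
view — which is why the body-outline extraction fills holes per axial
slice. The default grid is 16 x 64 x 64 at 4 mm; full-scale 512 x 512
grids are supported but not default.

The treatment-day anatomy is the planning phantom warped by a random
smooth field (i.i.d. Gaussian vectors, Gaussian-smoothed, rescaled so
the maximum displacement equals the bound, default 2.5 voxels ≈ 10 mm —
a realistic interfractional thoracic change). CBCT degradation adds a
smooth shading field (60 HU, 80 mm scale), angularly periodic streaks
(40 HU), a +150 HU lung offset (scatter raises apparent lung HU; the
sign is configurable since visual "dark lung" reports are
window-dependent), and 20 HU Gaussian noise, clipped to [-1024, 3000].
These amplitudes put the phantom CBCT's body-masked MAE against the true
day CT in the tens of HU, comparable to clinical CBCT/CT discrepancies.

What the phantom does *not* emulate: physically realistic scatter,
beam hardening or motion artifacts (its artifacts are additive and
low-dimensional), real tissue texture (organs are piecewise-constant),
and cross-patient anatomical diversity beyond parameter jitter. Passing
the phantom study therefore shows that the implementation learns and
evaluates correctly end-to-end, not that clinical image quality would
match any particular published figure.

## Dose and comparison machinery

The package consumes dose grids; it does not model a clinical dose
engine. `make_dose()` builds a toy but usable plan: 4-5 anisotropic
Gaussian beam profiles through the PTV centroid at evenly spaced
gantry angles, attenuated exponentially with radiological depth, scaled
so the PTV median equals the prescription (default 50.4 Gy). When given
a density image (HU), depth is integrated through relative electron
density `(HU + 1000)/1000` — so the same plan computed on dCT, CBCT and
sCT yields different grids, which is exactly what the gamma comparison
needs; without a density image the profile is purely geometric. When a
plan is recalculated on a second image of the same anatomy, the
monitor-unit scaling fixed on the reference grid must be reused
(`scale = attr(ref_dose, "dose_scale")`); rescaling each grid to the
prescription would cancel exactly the attenuation differences under
study.

`gamma_map()` implements the global (absolute) gamma index: per
reference voxel above a 10 % low-dose cutoff, the minimum over nearby
points of $\sqrt{d^2/\mathrm{DTA}^2 + \Delta D^2/(\mathrm{tol}\cdot
D_{norm})^2}$ with $D_{norm} = \max(\mathrm{ref})$, candidates on a
sub-voxel lattice (about DTA/3 steps) within a 3-DTA radius, sorted by
distance with early termination. Doubling both tolerance and DTA can
only shrink gamma, so passing rates are monotone from 1 mm/1 % to
3 mm/3 % — asserted as a property test. DVH curves are cumulative
volume fractions per ROI; scalar parameters (PTV D98, lung V5/V20, mean
lung dose, cord Dmax, heart V30, mean heart dose) come from sorted voxel
doses.

Image quality uses masked MAE/RMSE/PSNR within the patient outline
(threshold -400 HU, largest component, per-slice hole fill). The PSNR
peak is 3000 HU — the width of the clip window — a convention the
package states in its report headers since no universal choice exists.
Paired comparisons use the two-sided Wilcoxon signed-rank test with the
zero-discard convention; an all-tied input is reported as degenerate
rather than significant.

## Numerical choices and degenerate inputs

* All RNG flows from explicit seeds; dataset writing is bit-identical
  under a fixed seed, and the run manifest records config and checksums.
* `warp()` clamps out-of-bounds samples to the border; the field
  gradient is zeroed where clamped.
* Non-finite losses abort training with the offending term named.
* Empty ROIs are flagged, never silently reported as zeros; empty
  masks, zero reference doses, non-overlapping rigid pairs and
  out-of-range normalized values raise errors.
* Generator inputs must be divisible by 4 (two halvings); inference
  pads with normalized air and crops back, so arbitrary grids work.

## Scale of the shipped experiments

The test suite and the acceptance script run the whole study at phantom
scale: 8 training and 2 test patients of 16 x 64 x 64 voxels, 5 epochs
(640 generator iterations), 200-iteration registration-recovery, and
gamma criteria 1 mm/1 %, 2 mm/2 %, 3 mm/3 %. These sizes are the
package's declared desk-scale study conditions; they complete in minutes
on a single CPU while exercising every stage of the pipeline.

## Known limitations

* 2D slice-wise translation can leave through-plane inconsistencies;
  no sagittal/coronal fusion is attempted.
* The B-spline registration offers no diffeomorphic or
  inverse-consistency guarantee.
* The toy dose model has no scatter, build-up or penumbra physics; its
  purpose is to make dose-comparison machinery testable, not to predict
  clinical dose.
* Phantom realism limits are listed above; clinical figures from the
  literature are not reproducible from this package alone.
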