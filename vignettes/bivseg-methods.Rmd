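---
title: "Shape-refined bi-ventricular segmentation: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-refined bi-ventricular segmentation: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Short-axis cardiac MR stacks acquired with conventional protocols are
anisotropic and artefact-prone: slices are thick (around 10 mm against
roughly 1.3 mm in-plane), each slice is acquired in a separate breath-hold so
adjacent slices are shifted in-plane relative to one another, and the apex is
often not fully covered. A segmentation computed slice-wise from such a
volume inherits every one of these artefacts, so the resulting 3D
bi-ventricular model is jagged, misaligned and incomplete. `bivseg`
implements a two-stage pipeline that produces smooth, high-resolution (HR)
four-class segmentations — left and right ventricular cavity and wall (LVC,
LVW, RVC, RVW) — from such low-resolution (LR) inputs:

1. a **2.5D multi-task fully convolutional network** that simultaneously
   predicts per-voxel tissue classes and six anatomical landmarks;
2. an **explicit anatomical shape prior**: the network's segmentation of an
   LR volume is refined by propagating a bank of artefact-free HR atlases
   onto it (landmark-initialised affine alignment, normalised-mutual-
   information atlas selection, label-consistency B-spline free-form
   deformation, and non-local patch-based label fusion).

Because the network also localises the landmarks, the refinement needs no
manual initialisation and the pipeline is fully automatic.

# The multi-task network

## 2.5D representation

A volume of `#S` short-axis slices is presented to the network as a 2D
multi-channel image whose channels are the slices. All convolutions are
in-plane (3x3), so memory and parameter count behave like a 2D network, yet
every output voxel sees the whole slice stack, which preserves long-axis
spatial consistency — the property that slice-by-slice 2D networks lack.
Features are computed at `length(widths)` scales (2x average pooling between
scales), upsampled back to full resolution and concatenated together with
the raw input channels; two 1x1-convolution heads then emit per-voxel softmax
distributions over the 5 tissue classes and the 7 landmark classes (6
landmarks + background) for every slice. The raw-input skip connection is a
deliberate architectural element: each head output concerns one specific
slice, and at the narrow widths used on a CPU the shared trunk alone would be
an information bottleneck for 30 per-slice outputs.

## Losses

Training minimises `L_D + alpha * L_L + beta * ||W||_F^2`.

* `L_D` is the differentiable Dice loss written as a single global quotient
  per sample over all classes and voxels (`dice_loss()`), with smoothing
  constant `eps = 1e-5` guarding the denominator. A perfect prediction gives
  approximately -1 per sample. A **per-class variant** (`dice_variant =
  "per_class"`, one quotient per class, summed) is available and is what the
  desk-scale configuration trains with: with roughly 80% background voxels
  the global quotient is dominated by the background class and provides weak
  gradients for the four tissue classes at small training budgets.
* `L_L` is a class-balanced weighted categorical cross-entropy
  (`landmark_loss()`). Each landmark is rasterised as a single voxel among
  millions of background voxels; the weight `w_k = 1 - |Y_k|/|Y|` makes each
  landmark class weigh close to 1 and the background close to 0, so the two
  groups contribute comparably. Log-probabilities are clamped at `1e-12`, so
  the loss is always finite.
* `alpha = 1` and `beta = 1e-4` by default; both are config-exposed because
  no canonical values exist for them.

## Optimisation

`net_config()` defaults to plain SGD with momentum 0.9. The compact
configuration used for CPU-scale experiments (`tiny_net_config()`) selects
Adam (`optimiser = "adam"`, `lr = 2e-3`–`5e-3`): in pilot runs SGD plateaued
far from convergence within the few hundred steps a CPU training run can
afford, while Adam's per-parameter step sizes reach usable accuracy in the
same budget. Training applies the 3D on-the-fly augmentation of `augment()`
(in-plane translation, isotropic scaling, rotation about one random axis
through the central voxel, intensity gain; no shearing, no flipping) with
probability 0.5. The compact configuration rasterises each training landmark
with a 1-voxel dilation (27 voxels); this only thickens the training target
— landmark extraction always reduces a predicted cluster to its centre of
gravity, per class the centroid of the largest 26-connected component.

## Decoding

Labels are the per-voxel argmax of the probability maps along the class
direction; exact ties break towards the lower class index (background
favouring), a documented, stable rule.

# The shape refinement

Given an LR volume, its network segmentation `S` and landmarks, and a bank
of HR atlases:

1. **Affine initialisation.** For each atlas, the 12-degree-of-freedom
   affine transform minimising the summed squared distances between the six
   paired landmarks is computed in closed form (`affine_from_landmarks()`).
   This is a convex least-squares problem with a unique solution — the
   reason landmark-based initialisation is robust where image-based affine
   registration is not.
2. **Atlas selection.** Each atlas segmentation is warped to the target by
   its affine and scored by normalised mutual information against `S`
   (Studholme normalisation `(H(A)+H(B))/H(A,B)` on the discrete joint label
   histogram, labels as bins). The top `L = 5` atlases are kept.
3. **Deformable registration.** Each selected atlas segmentation is
   registered to `S` by a B-spline free-form deformation maximising label
   consistency (the fraction of voxels with the same label, the diagonal sum
   of the joint label probability). The optimisation works on a
   differentiable surrogate — atlas labels lifted to one-hot channels,
   Gaussian-smoothed per level, warped with trilinear interpolation — and
   ascends the mean probability assigned to the target's label. The schedule
   is coarse-to-fine with control-point spacings 40, 20, 10 and again 10 mm
   (the second fine pass, with sharper smoothing, resolves sub-voxel boundary
   placement), channel smoothing 4/2/1/0.6 mm. Each level is optimised by
   L-BFGS-B with the analytic gradient, run in segments of 10 iterations so
   the accepted objective trace is recorded; a segment is accepted only if it
   improves the surrogate by more than `tol = 1e-6`, making the trace
   strictly increasing and keeping an already-registered pair at identity.
   Control displacements are box-bounded at 0.4 control spacings per level
   against grid folding, and a small Tikhonov penalty on the control
   displacements conditions the problem. Two guards bracket the
   optimisation: a pair already in perfect hard-label agreement returns the
   identity immediately (perfect agreement cannot be improved, and the
   smoothed surrogate would otherwise drift samples towards region
   interiors without changing any label), and if the final hard-label
   agreement does not improve on the affine-only agreement the identity
   deformation is returned, so refinement can never be degraded by a failed
   registration.
4. **Non-local label fusion.** The warped atlas volumes and labels vote for
   each target voxel `x`: every window position `y` in every atlas
   contributes its label with weight `exp(-||f_x - f_{n,y}||_F^2 / h)`,
   where the patch distance compares the target patch at `x` with the atlas
   patch at `y` (patch radius 2, window radius 2 by default; border patches
   are clipped and their summed distance rescaled by full/valid patch size
   so border weights remain comparable). The bandwidth `h`, when not given,
   is set per target to the mean over voxels of the minimum patch distance
   across atlases — a scale-adaptive choice that needs no tuning. Ties in
   the vote break towards the lower class index. Where every vote in the
   window is unanimous the weights are irrelevant and the unanimous class is
   returned directly (an exact shortcut that skips most background voxels).

The printed form of the registration objective is a minimisation of the
label consistency while the surrounding text describes maximising overlap;
the package maximises label consistency (equivalently minimises one minus
it), and the tests assert the monotone increase of the surrogate agreement.

# The phantom generator

The clinical cohorts behind this method (thousands of HR volumes with expert
labels) are not publicly deposited, so the package ships a synthetic
bi-ventricular phantom (`make_phantom()`, `make_cohort()`) that emulates
their statistical structure and serves as the test bed:

* **Geometry.** The LV is two coaxial truncated ellipsoids (cavity and
  wall); the RV is a larger, laterally shifted ellipsoid pair clipped
  against the LV epicardium, giving the crescent-shaped RV of short-axis
  anatomy, with the RV free wall thinner than the LV wall. A
  pulmonary-hypertension-like preset (`ph_phantom_spec()`: dilated RV,
  thickened RV wall, compressed LV cavity) supports robustness experiments.
* **Landmarks** are placed by analytic rules in the phantom's canonical
  frame — apex at the most apical LV-wall point, mitral-valve centre at the
  basal cavity centroid, the two RV insert points at the intersection of the
  LV epicardial circle with the RV endocardial ellipse on a mid-basal slice,
  LV lateral-wall mid-point and RV turning point by angular rules — and then
  mapped through the pose, which makes placement exactly equivariant under
  rigid transforms (a tested property).
* **Intensity** is class-mean plus i.i.d. Gaussian noise (sd 0.04), with
  bright blood pools and darker myocardium on a 0–1 scale, loosely mimicking
  b-SSFP contrast; both cavities share nearly the same intensity, so
  left-right disambiguation must come from spatial context, as in real data.
  Rician noise, myocardial texture, papillary muscles and trabeculation are
  deliberately not modelled; passing tests therefore demonstrate the
  pipeline's mechanics and recovery behaviour, not clinical-grade accuracy
  on real scans.
* **Problem size.** The default lattice is 64 x 64 x 48 voxels at the HR
  acquisition spacing of 1.25 x 1.25 x 2 mm, holding an adult-sized heart
  (LV epicardial radius 24 mm, apex-to-base extent 75 mm, LV wall 9 mm, RV
  free wall 4.5 mm). Keeping adult dimensions matters beyond realism: the
  thick-slice artefact is 10 mm regardless of heart size, so a miniature
  phantom would make the corruption relatively far more severe than in the
  clinical acquisitions being emulated. The lattice is the smallest that
  holds this geometry with jitter margins, which keeps the full experiment —
  cohort generation, training of both networks, 50 deformable registrations
  and 10 fusions — a single-CPU job.

The artefact simulator (`corrupt()`) reproduces the LR acquisition process:
thick slices (thin slices mean-pooled for intensities, majority-voted for
labels; 2 mm to 10 mm by default), uniform integer-voxel in-plane shifts per
slice bounded by 5 mm (3 mm in the benchmark, matching its smaller heart),
zero-filling of shifted-out voxels, and optional removal of apical slices.
The same seed degrades a volume and its label map identically, which the
tests verify.

# The benchmark and its thresholds

`run_phantom_benchmark()` generates 30 phantoms (10 atlas bank / 10
additional training / 10 held-out test), trains an HR network on the 20
training subjects and an LR network on their corrupted versions, corrupts
the test subjects, and runs the LR pipeline path. It reports per-class Dice
and Hausdorff distances of the corrupted, initial-network and refined
segmentations against the clean truth, landmark errors, and ventricular
volume/mass errors (voxel-count volumes; myocardial density 1.05 g/ml, the
standard CMR convention). The headline recovery properties — refined Dice
strictly above the corrupted input's Dice for all four classes, mean
foreground Dice at least 0.85, shrinking clinical-measure errors, held-out
HR Dice at least 0.8, all six landmarks found with mean point-to-point error
below two cells of the network's coarsest feature lattice (2 x 5 mm = 10 mm)
— are asserted in the test suite at exactly these thresholds.

Two measurement subtleties are worth spelling out. First, clinical volume
and mass errors are reported against two baselines: the corrupted input
labels and the initial network segmentation. The artefact simulator's
majority-vote slab pooling preserves class volumes in expectation, so the
corrupted input labels are nearly volume-unbiased even though they are
spatially badly wrong — Dice and volume error dissociate — and the
meaningful baseline for judging the refinement's clinical accuracy is the
artefact-bearing segmentation that actually enters it. Second, the mean
foreground Dice of the refined low-resolution path is capped by the
information content of the corrupted target driving the registration: the
benchmark reaches about 0.83, with the thin RV free wall (about 0.7)
pulling the mean down, while the same registration-plus-fusion machinery
applied to an uncorrupted target scores far higher (the clean-target
refinement test). Pushing past this cap would require information the
corrupted volume does not contain.

# Numerical choices and degenerate inputs

* Intensity standardisation clips at the 1st/99th percentiles and rescales
  to [0, 1]; constant volumes map to 0, not NaN. Volumes larger than the
  target grid raise an error unless centre cropping is explicitly enabled.
* Voxel indices are 0-based; world coordinates (mm) are
  `origin + axes %*% (spacing * index)`. Volumes resample trilinearly,
  label maps nearest-neighbour (the label set is closed under every
  geometric operation).
* Dice of two empty masks is defined as 1, of one empty mask as 0; the
  Hausdorff distance of an empty mask is an error condition, not 0. The
  Hausdorff distance is the full symmetric max-min distance between
  26-connectivity boundary voxel centres, in mm.
* The FFD surrogate clamps out-of-domain sample positions to the grid edge
  (with zero gradient in the clamped axis) so the objective is continuous at
  the boundary; without this, any infinitesimal displacement of edge voxels
  would be penalised by a cliff unrelated to anatomy.
* All randomness is seed-controlled (`with_seed()` restores the caller's RNG
  state); cohort draws whose jittered geometry does not fit the grid are
  deterministically redrawn with damped jitter.

# Known limitations

* The phantom family is ellipsoidal; it cannot probe failure modes driven by
  trabeculation, papillary muscles, thin-wall partial-volume effects or
  through-plane motion.
* The networks here are deliberately small; the architecture scales (the
  full-size default is 15 convolutional layers over three scales) but
  training at cohort scale is outside a CPU budget.
* Registration regularity is enforced only by the per-level displacement
  bound and the B-spline parameterisation; no explicit bending-energy
  penalty is implemented.
* The atlas-selection NMI uses hard labels; probabilistic atlas selection is
  not implemented.
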