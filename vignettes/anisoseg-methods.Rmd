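---
title: "Cascaded anisotropic segmentation with test-time-augmentation uncertainty: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascaded anisotropic segmentation with test-time-augmentation uncertainty: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The segmentation problem

Gliomas present on multi-modal MR as three nested regions: the whole tumor
(edema plus everything inside it), the tumor core (whole tumor minus
infiltrative edema), and the contrast-enhancing core. FLAIR and T2 mostly
delineate the whole tumor; T1 and T1ce give better contrast for the core and
the enhancing region. `anisoseg` segments these subregions hierarchically:
three binary networks — WNet for the whole tumor, TNet for the core, ENet for
the enhancing core — run in sequence, each downstream network operating on the
margin-expanded bounding box of its predecessor's output and constrained by it
as a crisp (hard, intersecting) mask. The decomposition turns one four-class
problem into three easier binary ones and imposes the anatomical nesting
`enhancing ⊆ core ⊆ whole` by construction: `run_cascade()` assembles its
result with `masks_to_labels()`, which intersects before mapping to the label
codes 2 (edema), 1 (non-enhancing core), 4 (enhancing).

## Anisotropic 2.5D networks

Full 3D convolution at a useful receptive field is memory-hungry; pure 2D
ignores context across slices. The networks here decompose the 3×3×3 kernel
into intra-slice 3×3×1 and inter-slice 1×1×3 convolutions. Each backbone has
20 intra-slice convolutions in 10 residual blocks of two (with per-block
in-plane dilation), 4 inter-slice convolutions interleaved after blocks 2, 4,
6 and 8, and two in-plane downsampling layers (one for ENet, whose inputs are
smaller). Three 3×3×1 prediction heads tap the backbone at blocks 4, 7 and 10,
are upsampled in-plane to the input resolution, concatenated, and mapped to
`Cl = 2` class scores by a final 3×3×1 prediction layer. Backbone channel
width is `C0 = 32`.

The resulting receptive field is wide in-plane and narrow through-plane:
217×217×9 voxels for WNet/TNet and 113×113×9 for ENet. Because each network
sees little through-plane context, the same architecture is trained in the
axial, sagittal and coronal axis orders and the three softmax outputs are
averaged (`multiview_predict()`), recovering 3D context cheaply.

### Receptive-field arithmetic, exactly

`compute_receptive_field()` implements the usual recurrence over kernel
extent, dilation and stride as *exact interval propagation*: starting from one
output voxel it pushes the half-open index interval of influencing voxels
backwards through every layer, per axis, taking the union over prediction-head
paths. This matters because the naive closed-form recurrence mishandles parity
at strided and transposed layers. The implementation is cross-checked by
`probe_receptive_field()`, which realizes the network in a linear nonnegative
"probe mode" and backpropagates a unit sensitivity from a central output
voxel; the footprint of nonzero input gradient is the empirical receptive
field. The suite asserts analytic ≡ probe on the three default blueprints and
on dozens of random small ones.

Three structural choices were genuinely open and were fixed as follows:

* **Downsampling** is a 5×5×1 stride-2 convolution. A parity analysis of the
  exact interval recurrence shows that 2×2 or 3×3 strided kernels cannot
  produce the odd in-plane extents 217/113 under this topology; the 5×5
  strided convolution can, and large-kernel strided downsampling is standard
  practice.
* **Upsampling** of the intermediate prediction maps is an in-plane factor-2
  3×3×1 transposed convolution (through-plane resolution is never reduced, so
  nothing is resampled along z).
* **The dilation schedule** per residual block is not fully recoverable from
  the architecture description, so it is *constraint-derived*:
  `find_dilation_schedule()` measures each block's (affine) contribution to
  the in-plane extent and searches integer dilations reproducing the target
  extent exactly. The shipped defaults are `1,1,1,1,2,2,2,1,1,1` (WNet/TNet)
  and `1,1,1,2,2,2,1,1,1,1` (ENet); they are a valid solution of the
  constraint, not a claim about the original authors' values.

Other realization details: zero "same" padding everywhere so every layer
preserves spatial extent; each backbone convolution is followed by a
normalization layer and a PReLU activation. The normalization layer
standardizes each channel over the spatial field of the sample (instance
normalization). This keeps the native backend free of cross-sample coupling
and makes inference at batch size one identical to training behavior; it is
the one deliberate departure from classical batch normalization, chosen
because the backend processes samples independently. The first residual block
reconciles its 4-channel input with the `C0`-channel block output through a
zero-padded identity shortcut, keeping the backbone at exactly 20 intra-slice
convolutions. Deep-supervision heads feed the concatenation only; no auxiliary
loss terms are attached to them.

The `tiny` variant (4 blocks, `C0 = 4`, one downsampling layer) exists for
fast tests and the desk-scale benchmark; it is exempt from the
receptive-field invariant.

## Augmentation and test-time uncertainty

One acquired image is a single observation of the underlying anatomy under a
particular spatial configuration and noise draw. Both training and test-time
augmentation therefore sample, through the *same* code path
(`sample_transform()`, `apply_transform()`, `add_noise()`):

* rotation angles about the three axes, uniform on `[0, 2π)`,
* a Bernoulli(0.5) flip per axis,
* an isotropic scale factor uniform on `[0.8, 1.2]`,
* additive Gaussian intensity noise with standard deviation 0.05 on
  normalized intensities. (The prior is written N(0, 0.05); the 0.05 is read
  as a standard deviation, the convention of the prior work it follows, and
  is configurable.)

The transform composes flips, then Euler rotations x→y→z about the volume
center, then scaling; the composition order is a documented convention
covered by round-trip tests, since only the composition is specified by the
priors. An `in_plane_only` switch restricts rotation to the through-plane
axis for users worried about resampling strongly anisotropic data.

`tta_predict()` runs N Monte-Carlo draws (N = 20 at full scale), predicts on
each transformed noisy copy, re-aligns each prediction with the inverse
spatial transform (nearest-neighbour for labels; intensity noise needs no
inversion), and takes a per-voxel majority vote. Binary ties break toward
foreground — the "votes ≥ N/2" rule, favouring sensitivity — and hierarchical
labels are voted per structure and re-nested.

From the aligned prediction set come two uncertainty measures:

* **Voxel-wise entropy** (`voxel_entropy()`): the empirical label frequencies
  at a voxel give `H = −Σ p̂ ln p̂` in nats. H is 0 where all members agree
  and at most `ln N`. Entropy is computed per binary structure (three maps),
  matching the cascade's binary outputs; a combined-alphabet mode exists.
* **Volume variation coefficient** (`vvc()`): the standard deviation of the N
  structure volumes divided by their mean. The population (divide-by-N)
  standard deviation is the default — the variation-coefficient convention —
  with a sample-std switch. VVC is scale-invariant, so voxel counts and mm³
  give identical values. A structure absent from every member raises a
  distinct undefined-structure condition so callers can report "absent"
  rather than a number.

## Uncertainty-aware CRF post-processing

High-entropy voxels are often mis-segmented with confidence. The gate
(`uncertainty_gate()`) resets both class probabilities to 0.5 wherever
`H > 0.2` nats (strict inequality; the boundary case is left unchanged),
discarding unreliable unaries. A pairwise Potts CRF with Gaussian spatial and
appearance kernels over unaries `−ln p` is then relaxed by mean-field
iterations (`crf_refine()`); the naive baseline omits the gate. The CRF
formulation itself is the dense-Gaussian-kernel model this line of work
conventionally uses, since no specific formulation is prescribed; messages
are truncated to a configurable window (radius 4 by default), which is exact
on the small grids where the suite compares mean-field energies against
exhaustive enumeration (within 5% of the optimum on ≤ 12-voxel instances;
in practice it attains it). Post-processing is applied per binary structure
and re-nested, with the appearance kernel reading each structure's most
contrastive modality (FLAIR for whole tumor, T1ce for core and enhancing) by
default.

## Training contract

Networks are trained per (stage, view) with Adam (learning rate 1e-3, weight
decay 1e-7, batch size 5, 30k iterations at full scale) on the soft Dice
loss with squared-denominator terms and smoothing ε = 1e-5 (a linear-
denominator switch exists). Patches of 144×144×19 (WNet), 96×96×19 (TNet)
and 64×64×19 (ENet) are sampled 50/50 foreground-centered versus uniform —
the sampling bias is a documented choice, configurable — with the downstream
stages sampling inside the margin-expanded ground-truth bounding box of their
upstream structure, mirroring the cascade's crops (margin 5 voxels in-plane,
3 through-plane, configurable). Evaluation offers Dice (both-empty := 1, the
convention for absent structures; empty-vs-nonempty := 0) and Hausdorff
distance via brute-force surface matching with the maximum or the 95th
percentile; which percentile a given benchmark reports varies by convention,
so neither is asserted as canonical.

## The synthetic phantom cohort

Every stage is exercised without external data by `phantom_spec()` /
`generate_cohort()`: a large "brain" ellipsoid of nonzero tissue inside a
zero (skull-stripped) background, with three nested tumor ellipsoids mapped
to codes 2/1/4. FLAIR/T2 are elevated over the whole tumor, T1ce over the
enhancing core, with a milder core offset on T1/T1ce, plus i.i.d. Gaussian
noise per modality (default σ = 8 against offsets of 45–60, i.e. clearly
visible but noisy structure). Ellipsoids give analytic volume oracles; an
optional smooth random boundary deformation is available and off by default.
Cohorts randomize center, radii and contrast, and a quarter of cases are
LGG-like with an empty enhancing region, exercising the third stage's
empty-target path.

What the phantoms do *not* emulate: MRI bias fields, partial-volume effects,
anatomy outside the tumor, multi-focal lesions, and real lesion texture.
Tests passing on phantoms therefore demonstrate the correctness of the
machinery (geometry, masking, alignment, voting, formulas) and the
trainability of the networks — not clinical-grade accuracy on real data.

## Desk-scale benchmark sizes and numerical choices

The suite and the reproduction script run on one CPU, so the empirical
checks use scaled-down problem sizes chosen once: the `tiny` variant trained
on 20 phantoms (48×48×28 voxels) for 150 iterations at batch 3, evaluated on
5 held-out phantoms; TTA with N = 5 for the voting comparison; a 12-case
corruption-graded cohort with N = 8 draws for the error-versus-VVC rank
correlation, where prediction noise (random rotation/scale jitter of the
predicted labels) grows with a per-case corruption level so that prediction
diversity and error are co-monotone by construction. Receptive-field probing
uses 232×232×11 (WNet/TNet) and 120×120×11 (ENet) grids with a 2-channel
probe realization — the footprint does not depend on channel width.

Numerical conventions collected in one place: voxel indices are 0-based with
half-open bounding boxes; argmax binarization breaks probability ties toward
foreground, consistently with the voting tie-break; probabilities are floored
at 1e-6 before logs; normalization statistics use the nonzero (brain) region
by default — background zeros would dominate whole-volume statistics — with a
whole-volume switch; `0·ln 0 := 0` in the entropy; empty upstream masks
short-circuit downstream cascade stages, which the crisp mask would empty
anyway.

## Known limitations

* The native backend is CPU-bound R/Rcpp; the full-scale recipe (C0 = 32,
  30k iterations, three views) is provided but is cluster-tier in this
  backend. The tests exercise the tiny variant end-to-end.
* Mean-field is a local relaxation; optimality is only verified on
  enumerable instances.
* Rotation resampling uses trilinear/nearest interpolation with zero fill;
  round-trip alignment loses a small boundary shell (the suite measures a
  mean round-trip Dice ≈ 0.98 on phantom labels), which bounds the
  resolution of the TTA diversity estimates.
* The cascade propagates early-stage errors downstream by design (crisp
  masking); no cross-stage repair is attempted.
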