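# anisoseg

Hierarchical brain-tumor segmentation from multi-modal MRI with a cascade of
anisotropic 2.5D convolutional networks, plus Monte-Carlo test-time
augmentation (TTA) for aleatoric uncertainty estimation and
uncertainty-aware CRF post-processing.

`anisoseg` is for image-analysis researchers who want a fully inspectable,
CPU-runnable implementation of this segmentation pipeline: every stage — from
NIfTI case I/O to the network backend, the receptive-field calculus, the TTA
machinery, the uncertainty formulas and the mean-field CRF — is implemented
in R/Rcpp and exercised end-to-end on synthetic multi-modal phantoms, with no
external imaging data required.

## The method in brief

BraTS-style cases carry four co-registered, skull-stripped 1 mm isotropic
volumes (FLAIR, T1, T1ce, T2) and hierarchical labels
(enhancing core ⊆ tumor core ⊆ whole tumor; codes 4/1/2 plus background).
Three binary networks segment the hierarchy sequentially:

1. **WNet** segments the whole tumor on the full volume;
2. the volume is cropped to the bounding box of that segmentation and
   **TNet** segments the tumor core inside it, intersected with the
   whole-tumor mask (crisp mask);
3. the crop-and-mask step repeats for **ENet** and the enhancing core.

Each network is anisotropic ("2.5D"): 20 intra-slice 3×3×1 convolutions in
10 dilated residual blocks plus 4 inter-slice 1×1×3 convolutions, two
in-plane downsampling layers (one in ENet), and multi-scale prediction
heads. The receptive field is 217×217×9 voxels for WNet/TNet and 113×113×9
for ENet — wide in-plane, narrow through-plane — and models trained in the
axial, sagittal and coronal axis orders are fused by averaging softmax
outputs.

At test time the input is perturbed N times with transforms drawn from
priors (rotation `r ~ U(0, 2π)` per axis, flips `~ Bern(0.5)`, scale
`s ~ U(0.8, 1.2)`, intensity noise `~ N(0, 0.05)`); predictions are
inverse-aligned and majority-voted. The aligned prediction set
`𝒴 = {y_1, …, y_N}` yields

- voxel-wise entropy `H = −Σ_m p̂_m ln p̂_m` over the empirical label
  frequencies at each voxel (nats), and
- the structure-wise volume variation coefficient `VVC = σ_V / μ_V` over the
  N structure volumes.

Voxels with `H > 0.2` have their class probabilities reset to 0.5 before a
pairwise Gaussian-kernel CRF is relaxed by mean-field iterations
("uncertainty-aware CRF"); the naive CRF omits the gate.

## Worked example

```r
library(anisoseg)

# a reproducible synthetic cohort (nested ellipsoid tumors, four modalities)
train <- generate_cohort(20, phantom_spec(), seed = 11)
test  <- generate_cohort(5,  phantom_spec(), seed = 12, lgg_fraction = 0)

# train the fast 'tiny' cascade variant (a few minutes on one CPU)
preds <- train_cascade(train, tiny_train_config(iterations = 150,
                                                batch_size = 3, seed = 5))

# segment a held-out case, with TTA uncertainty
vol <- normalize_case(test[[1]]$volume)
cascade_pred <- function(v) run_cascade(v, preds)$labels
set.seed(99)
tta <- tta_predict(vol, cascade_pred, N = 5)

dice_score(labels_to_task_mask(label_volume(tta$vote), "whole"),
           labels_to_task_mask(test[[1]]$labels, "whole"))
#> [1] 0.9559016

structure_uncertainty(tta$set, "whole")$vvc
#> [1] 0.03893076

range(structure_entropy_maps(tta$set)$whole$H)
#> [1] 0.0000000 0.6730117
```

A run of this protocol over the five held-out phantoms gives mean whole-tumor
Dice ≈ 0.91 for the tiny cascade, with TTA voting matching or improving the
mean Dice across structures; high-entropy voxels concentrate on the tumor
boundary, and VVC rises with segmentation error across a corruption-graded
cohort. (Numbers vary slightly with seeds; the full-scale BraTS recipe —
`C0 = 32`, 30k iterations, three views — is configured in
`train_config()` but is GPU/cluster-tier.)

The receptive fields are available both analytically and empirically:

```r
compute_receptive_field(make_blueprint("WNet"))$extents   # 217 217 9
probe_receptive_field(make_blueprint("ENet"), c(120, 120, 11))$extents  # 113 113 9
```

## Command line

A thin Rscript wrapper ships in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/anisoseg.R", package="anisoseg"))')" \
    synth --n 5 --out cohort --seed 1
# subcommands: synth | train | predict | uncertainty | evaluate
```

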