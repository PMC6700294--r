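#' Bounding box of a task mask
#'
#' Tightest half-open `[lo, hi)` box (0-based voxel indices) containing all
#' positive voxels, expanded by a per-axis margin and clipped to the grid.
#'
#' @param mask a `task_mask` or binary array.
#' @param margin nonnegative integer margin per axis (recycled).
#' @return list with `lo` and `hi`, or `NULL` (the empty sentinel) for an
#'   all-zero mask.
#' @export
mask_bounding_box <- function(mask, margin = 0L) {
  m <- if (inherits(mask, "task_mask")) mask$mask else as_vol3d(mask)
  margin <- rep_len(as.integer(margin), 3L)
  idx <- which(m > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  lo <- pmax(apply(idx, 2, min) - 1L - margin, 0L)
  hi <- pmin(apply(idx, 2, max) - 1L + margin + 1L, dim(m))
  list(lo = as.integer(lo), hi = as.integer(hi))
}

crop_box <- function(x, box) {
  ix <- lapply(1:3, function(ax) (box$lo[ax] + 1L):box$hi[ax])
  if (inherits(x, "multimodal_volume")) {
    chans <- lapply(x$channels, function(ch) ch[ix[[1]], ix[[2]], ix[[3]], drop = FALSE])
    multimodal_volume(chans, spacing = x$spacing)
  } else if (length(dim(x)) == 4L) {
    x[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE]
  } else {
    x[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  }
}

embed_box <- function(x, box, shape, fill = 0) {
  out <- array(fill, dim = shape)
  out[(box$lo[1] + 1L):box$hi[1], (box$lo[2] + 1L):box$hi[2],
      (box$lo[3] + 1L):box$hi[3]] <- x
  out
}

# view permutations: the native (axial) order is (x, y, z) with z the
# through-plane axis; sagittal and coronal cyclically rotate the axes so the
# through-plane direction aligns with x and y respectively.
VIEW_PERMS <- list(axial = c(1L, 2L, 3L),
                   sagittal = c(2L, 3L, 1L),
                   coronal = c(3L, 1L, 2L))

#' Permute a volume into a view's canonical axis order
#'
#' @param x 3D or 4D array (trailing channel axis preserved).
#' @param view `"axial"`, `"sagittal"` or `"coronal"`.
#' @param inverse undo the permutation.
#' @export
permute_view <- function(x, view = c("axial", "sagittal", "coronal"),
                         inverse = FALSE) {
  view <- match.arg(view)
  p <- VIEW_PERMS[[view]]
  if (inverse) p <- order(p)
  if (length(dim(x)) == 4L) aperm(x, c(p, 4L)) else aperm(x, p)
}

#' Multi-view fusion
#'
#' Runs one predictor per orthogonal view on the correspondingly permuted
#' volume, permutes the class probabilities back to the native axis order,
#' and averages the softmax outputs with equal weights.
#'
#' @param volume a [multimodal_volume()] or 4D array.
#' @param predictors_by_view named list with entries `axial`, `sagittal`,
#'   `coronal`; each maps a 4D array (in its view's axis order) to a
#'   probability array `(x, y, z, Cl)`.
#' @return fused probability array.
#' @export
multiview_predict <- function(volume, predictors_by_view) {
  x <- if (inherits(volume, "multimodal_volume")) stack_channels(volume) else volume
  miss <- setdiff(names(VIEW_PERMS), names(predictors_by_view))
  if (length(miss) > 0)
    aniso_stop("config", "missing predictor for view(s): %s",
               paste(miss, collapse = ", "))
  acc <- NULL
  for (v in names(VIEW_PERMS)) {
    xp <- permute_view(x, v)
    pp <- predictors_by_view[[v]](xp)
    pb <- permute_view(pp, v, inverse = TRUE)
    acc <- if (is.null(acc)) pb else acc + pb
  }
  acc / length(VIEW_PERMS)
}

#' Sliding-window inference
#'
#' Tiles the volume with overlapping patches, runs the patch predictor on
#' each, and averages the class probabilities over all patches covering a
#' voxel.  Volumes smaller than the patch are zero-padded and cropped back.
#'
#' @param volume 4D array `(x, y, z, channels)` or [multimodal_volume()].
#' @param predictor function mapping a 4D patch to a probability array of
#'   identical spatial extent.
#' @param patch_extent 3-vector patch size.
#' @param stride 3-vector stride (must not exceed the patch extent).
#' @return probability array `(x, y, z, Cl)`.
#' @export
sliding_window_infer <- function(volume, predictor, patch_extent,
                                 stride = patch_extent) {
  x <- if (inherits(volume, "multimodal_volume")) stack_channels(volume) else volume
  patch_extent <- rep_len(as.integer(patch_extent), 3L)
  stride <- rep_len(as.integer(stride), 3L)
  if (any(stride > patch_extent))
    aniso_stop("config", "stride must not exceed the patch extent")
  d <- dim(x)[1:3]
  pad <- pmax(patch_extent - d, 0L)
  if (any(pad > 0)) {
    xp <- array(0, dim = c(d + pad, dim(x)[4]))
    xp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ] <- x
    x <- xp
  }
  dp <- dim(x)[1:3]
  starts <- lapply(1:3, function(ax) {
    s <- seq(0L, max(dp[ax] - patch_extent[ax], 0L), by = stride[ax])
    if (s[length(s)] + patch_extent[ax] < dp[ax])
      s <- c(s, dp[ax] - patch_extent[ax])
    unique(s)
  })
  accum <- NULL; wsum <- array(0, dim = dp)
  for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]]) {
    ix <- sx + seq_len(patch_extent[1]); iy <- sy + seq_len(patch_extent[2])
    iz <- sz + seq_len(patch_extent[3])
    p <- predictor(x[ix, iy, iz, , drop = FALSE])
    if (is.null(accum)) accum <- array(0, dim = c(dp, dim(p)[4]))
    accum[ix, iy, iz, ] <- accum[ix, iy, iz, , drop = FALSE] + p
    wsum[ix, iy, iz] <- wsum[ix, iy, iz] + 1
  }
  for (ch in seq_len(dim(accum)[4]))
    accum[, , , ch] <- accum[, , , ch] / wsum
  accum[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), , drop = FALSE]
}

binarize_prob <- function(prob) {
  # argmax with ties toward foreground (p_fg >= 0.5 for the binary case)
  (prob[, , , 2] >= prob[, , , 1]) + 0L
}

#' Run the triple cascade
#'
#' WNet segments the whole tumor on the full volume; the volume is cropped to
#' the bounding box of that segmentation (plus margin), TNet segments the
#' tumor core inside the crop and is intersected with the whole-tumor mask
#' (crisp mask); the crop-and-mask step repeats for ENet and the enhancing
#' core.  A stage whose upstream mask is empty short-circuits: downstream
#' stages are skipped and return empty.  The final hierarchical labels are
#' assembled with [masks_to_labels()], so the nesting invariant holds by
#' construction.
#'
#' @param volume a [multimodal_volume()] (normalized intensities).
#' @param stage_predictors named list `whole`, `core`, `enhancing`; each maps
#'   a [multimodal_volume()] to a binary-class probability array
#'   `(x, y, z, 2)` (background, foreground).
#' @param margin crop margin per axis in voxels (default 5 in-plane, 3
#'   through-plane).
#' @return list with `labels` (a [label_volume()]) and `probabilities`
#'   (per-stage foreground-probability arrays on the full grid).
#' @export
run_cascade <- function(volume, stage_predictors,
                        margin = c(5L, 5L, 3L)) {
  for (s in STRUCTURES)
    if (!is.function(stage_predictors[[s]]))
      aniso_stop("config", "missing stage predictor: %s", s)
  shp <- volume$shape
  probs <- list()
  run_stage <- function(s, vol) {
    p <- tryCatch(stage_predictors[[s]](vol), error = function(e)
      aniso_stop("input", "stage %s failed: %s", s, conditionMessage(e)))
    p
  }
  # stage 1: whole tumor on the full volume
  p_whole <- run_stage("whole", volume)
  whole <- binarize_prob(p_whole)
  probs$whole <- p_whole[, , , 2]
  core <- array(0L, dim = shp); enh <- array(0L, dim = shp)
  probs$core <- array(0, dim = shp); probs$enhancing <- array(0, dim = shp)
  box1 <- mask_bounding_box(whole, margin)
  if (!is.null(box1)) {
    vol1 <- crop_box(volume, box1)
    attr(vol1, "crop_box") <- box1
    p_core <- run_stage("core", vol1)
    core_c <- binarize_prob(p_core)
    core_full <- embed_box(core_c, box1, shp)
    core <- core_full * whole                    # crisp mask
    probs$core <- embed_box(p_core[, , , 2], box1, shp)
    box2 <- mask_bounding_box(core, margin)
    if (!is.null(box2)) {
      vol2 <- crop_box(volume, box2)
      attr(vol2, "crop_box") <- box2
      p_enh <- run_stage("enhancing", vol2)
      enh_c <- binarize_prob(p_enh)
      enh <- embed_box(enh_c, box2, shp) * core  # crisp mask
      probs$enhancing <- embed_box(p_enh[, , , 2], box2, shp)
    }
  }
  labels <- masks_to_labels(whole, core, enh, spacing = volume$spacing)
  list(labels = labels, probabilities = probs)
}

#' Build a stage predictor from a realized network
#'
#' Wraps a network (or one per view for multi-view fusion) into the
#' `multimodal_volume -> probability` interface expected by
#' [run_cascade()], using sliding-window tiling when a patch extent is given
#' and whole-volume inference otherwise.
#'
#' @param net an `aniso_net`, or a named list of nets per view
#'   (`axial`, `sagittal`, `coronal`).
#' @param patch_extent optional 3-vector patch size for tiling.
#' @param stride tiling stride (defaults to half the patch).
#' @return function mapping a volume to a `(x, y, z, 2)` probability array.
#' @export
as_stage_predictor <- function(net, patch_extent = NULL, stride = NULL) {
  infer_one <- function(network, x4d) {
    if (is.null(patch_extent)) net_predict(network, x4d)
    else sliding_window_infer(x4d, function(p) net_predict(network, p),
                              patch_extent, stride %||% pmax(patch_extent %/% 2L, 1L))
  }
  if (inherits(net, "aniso_net")) {
    function(volume) {
      x <- if (inherits(volume, "multimodal_volume")) stack_channels(volume) else volume
      infer_one(net, x)
    }
  } else {
    preds <- lapply(net, function(n) function(xp) infer_one(n, xp))
    function(volume) multiview_predict(volume, preds)
  }
}

#' Oracle stage predictors from ground truth
#'
#' Maps each stage to the ground-truth binary mask as a 0/1 probability
#' volume — the identity-composition reference for cascade tests.
#'
#' @param labels a [label_volume()] (full-grid ground truth).
#' @param full_volume the full-grid [multimodal_volume()] the cascade runs
#'   on; cascade crops are located via the crop-box attribute the engine
#'   attaches (with a scan fallback for externally cropped inputs).
#' @keywords internal
#' @export
oracle_stage_predictors <- function(labels, full_volume) {
  full_flair <- full_volume$channels$FLAIR
  make <- function(structure) {
    truth <- labels_to_task_mask(labels, structure)$mask
    function(volume) {
      box <- attr(volume, "crop_box") %||%
        locate_subvolume(full_flair, volume$channels$FLAIR)
      m <- crop_box(truth, box)
      p <- array(0, dim = c(dim(m), 2L))
      p[, , , 1] <- 1 - m; p[, , , 2] <- m
      p
    }
  }
  setNames(lapply(STRUCTURES, make), STRUCTURES)
}

# Locate a cropped subvolume inside its parent by scanning candidate offsets
# (used only by the oracle predictor on phantom-scale grids).
locate_subvolume <- function(parent, sub) {
  dp <- dim(parent); ds <- dim(sub)
  if (identical(dp, ds)) return(list(lo = c(0L, 0L, 0L), hi = dp))
  for (ox in 0:(dp[1] - ds[1])) for (oy in 0:(dp[2] - ds[2]))
    for (oz in 0:(dp[3] - ds[3])) {
      if (parent[ox + 1, oy + 1, oz + 1] != sub[1, 1, 1]) next
      box <- list(lo = c(ox, oy, oz), hi = c(ox, oy, oz) + ds)
      if (identical(crop_box(parent, box), sub)) return(box)
    }
  aniso_stop("input", "subvolume not found in parent grid")
}
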