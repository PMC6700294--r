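#' Soft Dice loss
#'
#' `1 - (2 sum(p g) + eps) / (sum(p^2) + sum(g^2) + eps)` (squared-term
#' denominator; set `squared = FALSE` for the linear variant
#' `sum(p) + sum(g)`).  Value in `[0, 1]` up to the smoothing term.
#'
#' @param prob_fg foreground probability array in `[0, 1]`.
#' @param target binary target array of the same shape.
#' @param eps smoothing constant.
#' @param squared use squared denominator terms.
#' @export
dice_loss <- function(prob_fg, target, eps = 1e-5, squared = TRUE) {
  if (inherits(target, "task_mask")) target <- target$mask
  prob_fg <- as_vol3d(prob_fg); target <- as_vol3d(target)
  stopifnot_same_shape(prob_fg, target, "probability/target")
  num <- 2 * sum(prob_fg * target) + eps
  den <- if (squared) sum(prob_fg^2) + sum(target^2) + eps
         else sum(prob_fg) + sum(target) + eps
  1 - num / den
}

# gradient of dice_loss w.r.t. prob_fg (squared variant)
dice_loss_grad <- function(prob_fg, target, eps = 1e-5) {
  num <- 2 * sum(prob_fg * target) + eps
  den <- sum(prob_fg^2) + sum(target^2) + eps
  -(2 * target * den - num * 2 * prob_fg) / den^2
}

#' Dice overlap score
#'
#' `2|A n B| / (|A| + |B|)`.  Two empty masks score 1 (the structure is
#' correctly found absent); empty-versus-nonempty scores 0.
#'
#' @param a,b binary masks (`task_mask` or arrays) of one shape.
#' @export
dice_score <- function(a, b) {
  if (inherits(a, "task_mask")) a <- a$mask
  if (inherits(b, "task_mask")) b <- b$mask
  a <- as_vol3d(a); b <- as_vol3d(b)
  stopifnot_same_shape(a, b, "masks")
  sa <- sum(a); sb <- sum(b)
  if (sa == 0 && sb == 0) return(1.0)
  2 * sum(a * b) / (sa + sb)
}

# Face-connected boundary voxels of a binary mask, as 0-based coordinates.
surface_voxels <- function(mask) {
  d <- dim(mask)
  shift <- function(m, ax, by) {
    idx <- rep(list(quote(expr = )), 3)
    n <- d[ax]
    sel <- pmin(pmax(seq_len(n) + by, 1L), n)
    idx[[ax]] <- sel
    do.call(`[`, c(list(m), idx, list(drop = FALSE)))
  }
  interior <- mask > 0
  for (ax in 1:3) for (by in c(-1L, 1L))
    interior <- interior & (shift(mask, ax, by) > 0)
  # border voxels of the grid with mask on are boundary by convention
  surf <- (mask > 0) & !interior
  which(surf, arr.ind = TRUE) - 1L
}

#' Hausdorff distance between two masks
#'
#' Symmetric surface distance in millimetres via brute-force nearest surface
#' voxel matching.  `percentile = 100` gives the classical maximum; 95 the
#' robust HD95 (per-direction percentile of the directed surface distances,
#' then the maximum of the two directions).
#'
#' @param a,b binary masks of one shape.
#' @param percentile 100 or 95.
#' @param spacing voxel spacing in mm.
#' @export
hausdorff_distance <- function(a, b, percentile = 100, spacing = NULL) {
  sp <- spacing %||%
    (if (inherits(a, "task_mask")) a$spacing else c(1, 1, 1))
  if (inherits(a, "task_mask")) a <- a$mask
  if (inherits(b, "task_mask")) b <- b$mask
  a <- as_vol3d(a); b <- as_vol3d(b)
  stopifnot_same_shape(a, b, "masks")
  if (sum(a) == 0 || sum(b) == 0)
    aniso_stop("undefined_structure",
               "Hausdorff distance undefined for an empty mask")
  pa <- surface_voxels(a); pb <- surface_voxels(b)
  dab <- directed_surface_dists(pa, pb, sp)
  dba <- directed_surface_dists(pb, pa, sp)
  pct <- function(v) if (percentile >= 100) max(v)
    else as.numeric(quantile(v, percentile / 100, type = 7))
  max(pct(dab), pct(dba))
}
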