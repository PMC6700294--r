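#' CRF parameters
#'
#' Pairwise Potts model with a Gaussian spatial kernel and a Gaussian
#' appearance (intensity) kernel over unaries `-ln p`, relaxed by mean-field
#' iterations.  Messages are computed within a truncated window; a radius
#' covering the grid makes the model fully connected (the regime used by the
#' small-instance energy tests).
#'
#' @param spatial_weight weight of the spatial smoothness kernel.
#' @param spatial_sigma bandwidth of the spatial kernel (voxels).
#' @param appearance_weight weight of the appearance kernel.
#' @param appearance_sigma_spatial spatial bandwidth of the appearance kernel
#'   (voxels).
#' @param appearance_sigma_intensity intensity bandwidth (on normalized,
#'   z-scored intensities).
#' @param iterations mean-field iteration count.
#' @param theta voxel-entropy threshold (nats) of the uncertainty gate.
#' @param radius message-window truncation radius (voxels).
#' @export
crf_params <- function(spatial_weight = 2, spatial_sigma = 1.5,
                       appearance_weight = 2, appearance_sigma_spatial = 4,
                       appearance_sigma_intensity = 0.5,
                       iterations = 5, theta = 0.2, radius = 4L) {
  if (spatial_weight < 0 || appearance_weight < 0)
    aniso_stop("config", "pairwise weights must be nonnegative")
  if (iterations < 1) aniso_stop("config", "iterations must be >= 1")
  if (theta < 0) aniso_stop("config", "uncertainty threshold must be >= 0")
  structure(list(spatial_weight = spatial_weight, spatial_sigma = spatial_sigma,
                 appearance_weight = appearance_weight,
                 appearance_sigma_spatial = appearance_sigma_spatial,
                 appearance_sigma_intensity = appearance_sigma_intensity,
                 iterations = as.integer(iterations), theta = theta,
                 radius = as.integer(radius)),
            class = "crf_params")
}

as_prob2 <- function(prob) {
  # accept (x,y,z,2) arrays or a foreground-probability 3D array
  if (length(dim(prob)) == 3L) {
    p <- array(0, dim = c(dim(prob), 2L))
    p[, , , 1] <- 1 - prob; p[, , , 2] <- prob
    p
  } else prob
}

#' Uncertainty gate
#'
#' Resets both class probabilities to 0.5 wherever the voxel-wise entropy
#' exceeds the threshold (strictly: `H > theta`; a voxel at exactly the
#' threshold is left unchanged).  Idempotent.
#'
#' @param prob binary-class probability volume (`(x,y,z,2)` array or
#'   foreground 3D array).
#' @param H voxel-entropy map (`uncertainty_map` or 3D array, nats).
#' @param theta threshold in nats (default 0.2).
#' @return gated `(x,y,z,2)` probability array.
#' @export
uncertainty_gate <- function(prob, H, theta = 0.2) {
  p <- as_prob2(prob)
  h <- if (inherits(H, "uncertainty_map")) H$H else as_vol3d(H)
  if (!identical(dim(p)[1:3], dim(h)))
    aniso_stop("format", "probability volume and uncertainty map shapes differ")
  hot <- h > theta
  p1 <- p[, , , 1]; p2 <- p[, , , 2]
  p1[hot] <- 0.5; p2[hot] <- 0.5
  p[, , , 1] <- p1; p[, , , 2] <- p2
  p
}

#' Mean-field CRF refinement
#'
#' Relaxes the pairwise model of [crf_params()] over unaries `-ln p` and
#' returns the argmax labeling as a binary mask.  With all pairwise weights
#' zero the result is exactly the argmax of the input probabilities.
#' Probabilities are floored at `1e-6` before taking logs.
#'
#' @param prob binary-class probability volume.
#' @param image reference intensity channel (3D array or
#'   [multimodal_volume()] — then `channel` selects the modality).
#' @param params a [crf_params()].
#' @param channel appearance-kernel modality when `image` is multi-modal.
#' @param task task name attached to the returned mask.
#' @return a `task_mask`.
#' @export
crf_refine <- function(prob, image, params = crf_params(),
                       channel = "FLAIR", task = "whole") {
  p <- as_prob2(prob)
  img <- if (inherits(image, "multimodal_volume")) image$channels[[channel]]
         else as_vol3d(image)
  if (!identical(dim(p)[1:3], dim(img)))
    aniso_stop("format", "probability and image shapes differ")
  p <- pmax(p, 1e-6)
  unary <- -log(p)
  # Mean field is a local relaxation; run it from the unary and the uniform
  # initialization and keep the labeling with the lower model energy.
  run <- function(init_uniform) {
    Q <- crf_meanfield(unary, dim(img), img,
                       params$spatial_weight, params$spatial_sigma,
                       params$appearance_weight, params$appearance_sigma_spatial,
                       params$appearance_sigma_intensity,
                       params$radius, params$iterations, init_uniform)
    (Q[, , , 2] >= Q[, , , 1]) + 0L
  }
  cands <- list(run(0L), run(1L))
  # the Potts pairwise term is invariant under global label exchange, so mean
  # field can lock into the wrong polarity; offer the complements as well
  cands <- c(cands, lapply(cands, function(lb) 1L - lb))
  if (params$spatial_weight == 0 && params$appearance_weight == 0) {
    lab <- cands[[1]]
  } else {
    energies <- vapply(cands, function(lb)
      crf_energy_window(as.integer(lb), unary, dim(img), img,
                        params$spatial_weight, params$spatial_sigma,
                        params$appearance_weight,
                        params$appearance_sigma_spatial,
                        params$appearance_sigma_intensity, params$radius),
      numeric(1))
    lab <- cands[[which.min(energies)]]
  }
  task_mask(array(lab, dim = dim(img)), task)
}

#' Uncertainty-aware CRF
#'
#' [uncertainty_gate()] followed by [crf_refine()]: voxels whose test-time-
#' augmentation entropy exceeds `params$theta` lose their (possibly
#' confidently wrong) unaries and are relabeled from image evidence and
#' spatial context.  The naive baseline is `crf_refine` without gating
#' (equivalently `theta = Inf`).
#'
#' @inheritParams crf_refine
#' @param H voxel-entropy map.
#' @export
uncertainty_aware_crf <- function(prob, H, image, params = crf_params(),
                                  channel = "FLAIR", task = "whole") {
  gated <- uncertainty_gate(prob, H, params$theta)
  crf_refine(gated, image, params, channel = channel, task = task)
}

#' Exact energy of a labeling under the dense CRF model
#'
#' Fully-connected pairwise energy (no window truncation); used as an
#' enumeration oracle on tiny instances.
#'
#' @param labels binary 3D array.
#' @inheritParams crf_refine
#' @export
crf_labeling_energy <- function(labels, prob, image, params = crf_params()) {
  p <- pmax(as_prob2(prob), 1e-6)
  img <- if (inherits(image, "multimodal_volume")) image$channels$FLAIR
         else as_vol3d(image)
  lab <- if (inherits(labels, "task_mask")) labels$mask else as_vol3d(labels)
  crf_energy(as.integer(lab), -log(p), dim(img), img,
             params$spatial_weight, params$spatial_sigma,
             params$appearance_weight, params$appearance_sigma_spatial,
             params$appearance_sigma_intensity)
}

#' Post-process cascade output with the uncertainty-aware CRF
#'
#' Applies per-structure gating and refinement to the three binary stages of
#' a cascade result, then re-nests the refined masks with
#' [masks_to_labels()].  The appearance kernel uses each structure's most
#' contrastive modality (FLAIR for whole tumor, T1ce for core and enhancing)
#' unless overridden.
#'
#' @param cascade_out result of [run_cascade()].
#' @param entropy_maps per-structure `uncertainty_map`s (e.g. from
#'   [structure_entropy_maps()]); `NULL` entries skip gating for that
#'   structure.
#' @param volume the (normalized) [multimodal_volume()].
#' @param params a [crf_params()].
#' @param channels named structure-to-modality map for the appearance kernel.
#' @return a [label_volume()].
#' @export
postprocess_cascade <- function(cascade_out, entropy_maps, volume,
                                params = crf_params(),
                                channels = c(whole = "FLAIR", core = "T1ce",
                                             enhancing = "T1ce")) {
  masks <- list()
  for (s in STRUCTURES) {
    prob <- cascade_out$probabilities[[s]]
    H <- entropy_maps[[s]]
    gated <- if (is.null(H)) as_prob2(prob)
             else uncertainty_gate(prob, H, params$theta)
    masks[[s]] <- crf_refine(gated, volume, params, channel = channels[[s]],
                             task = s)
  }
  masks_to_labels(masks$whole, masks$core, masks$enhancing,
                  spacing = volume$spacing)
}
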