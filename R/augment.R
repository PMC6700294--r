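#' Sample spatial/intensity transform parameters
#'
#' Draws one set of augmentation parameters from the priors used for both
#' training augmentation and Monte-Carlo test-time augmentation: rotation
#' angles about the three spatial axes uniform on `[0, 2*pi)`, an independent
#' Bernoulli(0.5) flip per axis, an isotropic scale factor uniform on
#' `[0.8, 1.2]`, and additive Gaussian intensity noise with standard
#' deviation `noise_std` (0.05 on normalized intensities).
#'
#' @param noise_std standard deviation of the intensity noise prior.
#' @param in_plane_only if `TRUE`, only the through-plane rotation angle is
#'   drawn (in-plane rotation), the other two are 0.
#' @return object of class `transform_params` with fields `r`, `f`, `s`,
#'   `noise_std`.
#' @export
sample_transform <- function(noise_std = 0.05, in_plane_only = FALSE) {
  r <- runif(3, 0, 2 * pi)
  if (in_plane_only) r[1:2] <- 0
  structure(list(r = r,
                 f = runif(3) < 0.5,
                 s = runif(1, 0.8, 1.2),
                 noise_std = noise_std),
            class = "transform_params")
}

#' @rdname sample_transform
#' @export
identity_transform <- function(noise_std = 0) {
  structure(list(r = c(0, 0, 0), f = c(FALSE, FALSE, FALSE), s = 1,
                 noise_std = noise_std),
            class = "transform_params")
}

rot_mat <- function(ax, th) {
  c0 <- cos(th); s0 <- sin(th)
  m <- diag(3)
  ij <- switch(ax, x = c(2, 3), y = c(1, 3), z = c(1, 2))
  m[ij[1], ij[1]] <- c0; m[ij[2], ij[2]] <- c0
  m[ij[1], ij[2]] <- -s0; m[ij[2], ij[1]] <- s0
  m
}

# Combined linear map of the transform: flips, then rotations applied in the
# order x, then y, then z about the volume center, then isotropic scaling.
transform_matrix <- function(params) {
  f <- diag(ifelse(params$f, -1, 1))
  params$s * rot_mat("z", params$r[3]) %*% rot_mat("y", params$r[2]) %*%
    rot_mat("x", params$r[1]) %*% f
}

apply_transform_array <- function(arr, M, interpolation) {
  arr <- as_vol3d(arr)
  ctr <- (dim(arr) - 1) / 2
  # resampling pulls values: out(v) = in(M^-1 (v - c) + c)
  affine_resample(arr, dim(arr), solve(M), ctr,
                  as.integer(interpolation == "nearest"))
}

#' Apply a spatial transform to a volume
#'
#' Composition order: flips, then Euler rotations x->y->z about the volume
#' center, then isotropic scaling about the center.  Regions mapped from
#' outside the grid are zero-filled.
#'
#' @param volume a [multimodal_volume()], [label_volume()], `task_mask`, or a
#'   plain 3D array.
#' @param params a `transform_params` object.
#' @param interpolation `"linear"` (intensities) or `"nearest"` (labels).
#' @export
apply_transform <- function(volume, params,
                            interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (!all(is.finite(c(params$r, params$s))) || params$s <= 0)
    aniso_stop("transform", "non-finite or degenerate transform parameters")
  M <- transform_matrix(params)
  transform_with_matrix(volume, M, interpolation)
}

#' @rdname apply_transform
#' @export
invert_transform <- function(volume, params,
                             interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (params$s == 0) aniso_stop("transform", "scale factor 0 cannot be inverted")
  M <- solve(transform_matrix(params))
  transform_with_matrix(volume, M, interpolation)
}

transform_with_matrix <- function(volume, M, interpolation) {
  if (inherits(volume, "multimodal_volume")) {
    out <- volume
    for (m in MODALITIES)
      out$channels[[m]] <- apply_transform_array(volume$channels[[m]], M,
                                                 interpolation)
    out
  } else if (inherits(volume, "label_volume")) {
    lab <- apply_transform_array(volume$labels, M, "nearest")
    label_volume(lab, spacing = volume$spacing)
  } else if (inherits(volume, "task_mask")) {
    task_mask(apply_transform_array(volume$mask, M, "nearest"), volume$task,
              spacing = volume$spacing)
  } else {
    apply_transform_array(volume, M, interpolation)
  }
}

#' Add Gaussian intensity noise
#'
#' I.i.d. additive noise drawn independently per modality, intended for
#' normalized intensities (prior standard deviation 0.05).
#'
#' @param volume a [multimodal_volume()] or 3D array.
#' @param noise_std noise standard deviation.
#' @export
add_noise <- function(volume, noise_std = 0.05) {
  if (noise_std == 0) return(volume)
  if (inherits(volume, "multimodal_volume")) {
    out <- volume
    for (m in MODALITIES)
      out$channels[[m]] <- volume$channels[[m]] +
        array(rnorm(prod(volume$shape), 0, noise_std), dim = volume$shape)
    out
  } else {
    volume + array(rnorm(length(volume), 0, noise_std), dim = dim(volume))
  }
}

# Single augmentation step shared verbatim between training augmentation and
# test-time augmentation: spatial transform plus intensity noise.
augment_case <- function(volume, params, labels = NULL) {
  tv <- apply_transform(volume, params, "linear")
  tv <- add_noise(tv, params$noise_std)
  if (is.null(labels)) return(list(volume = tv))
  list(volume = tv, labels = apply_transform(labels, params, "nearest"))
}

#' Prediction set
#'
#' Houses the N Monte-Carlo segmentations of one case, all re-aligned to the
#' original voxel grid.
#'
#' @param members list of aligned segmentations (binary arrays, `task_mask`s
#'   or [label_volume()]s).
#' @export
prediction_set <- function(members) {
  if (length(members) < 1) aniso_stop("input", "prediction set needs N >= 1 members")
  arrs <- lapply(members, function(m) {
    if (inherits(m, "label_volume")) m$labels
    else if (inherits(m, "task_mask")) m$mask
    else as_vol3d(m)
  })
  shp <- dim(arrs[[1]])
  for (a in arrs) if (!identical(dim(a), shp))
    aniso_stop("format", "prediction-set members must share the case shape")
  structure(list(members = arrs, N = length(arrs), shape = shp),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat("<prediction_set> N =", x$N, "members of", paste(x$shape, collapse = "x"), "\n")
  invisible(x)
}

#' Majority vote over a prediction set
#'
#' Per voxel the modal label.  For binary members a tie is broken toward
#' foreground (the rule "foreground if votes >= N/2"); for hierarchical label
#' volumes the vote is taken per binary structure (whole, core, enhancing)
#' with the same tie-break, and the structures are re-nested with
#' [masks_to_labels()].
#'
#' @param set a [prediction_set()].
#' @param tie one of `"foreground"` (default) or `"background"`.
#' @return 3D integer array of voted labels.
#' @export
majority_vote <- function(set, tie = c("foreground", "background")) {
  tie <- match.arg(tie)
  stopifnot(inherits(set, "prediction_set"))
  labs <- sort(unique(unlist(lapply(set$members, function(m) unique(as.vector(m))))))
  vote_binary <- function(masks) {
    s <- Reduce(`+`, masks)
    thr <- set$N / 2
    if (tie == "foreground") (s >= thr) + 0L else (s > thr) + 0L
  }
  if (all(labs %in% c(0, 1))) {
    v <- vote_binary(set$members)
    storage.mode(v) <- "integer"
    return(array(v, dim = set$shape))
  }
  masks <- lapply(STRUCTURES, function(s) {
    codes <- switch(s, whole = c(1, 2, 4), core = c(1, 4), enhancing = 4)
    vote_binary(lapply(set$members, function(m)
      array(as.integer(m %in% codes), dim = set$shape)))
  })
  masks_to_labels(masks[[1]], masks[[2]], masks[[3]])$labels
}

#' Monte-Carlo test-time augmentation
#'
#' For each of `N` draws, samples transform parameters from the priors,
#' produces a transformed noisy copy of the input, predicts, and re-aligns
#' the prediction to the original grid with the inverse spatial transform
#' (nearest-neighbour for labels).  Returns the aligned prediction set and
#' its majority vote.
#'
#' @param volume a [multimodal_volume()] (normalized intensities).
#' @param predictor function mapping a [multimodal_volume()] to a labeling
#'   (3D array, `task_mask`, or [label_volume()]).
#' @param N Monte-Carlo simulation count (default 20).
#' @param noise_std intensity-noise prior standard deviation.
#' @param in_plane_only restrict rotations to the through-plane axis.
#' @param identity_transforms if `TRUE` all draws use the identity transform
#'   (diagnostic mode; with `N = 1` this equals plain prediction).
#' @return list with `set` (a [prediction_set()]) and `vote` (3D array).
#' @export
tta_predict <- function(volume, predictor, N = 20, noise_std = 0.05,
                        in_plane_only = FALSE, identity_transforms = FALSE) {
  if (N < 1) aniso_stop("input", "N must be >= 1")
  members <- vector("list", N)
  for (i in seq_len(N)) {
    params <- if (identity_transforms) identity_transform(noise_std)
              else sample_transform(noise_std, in_plane_only)
    aug <- augment_case(volume, params)$volume
    pred <- tryCatch(predictor(aug), error = function(e)
      aniso_stop("input", "predictor failed at draw %d: %s", i,
                 conditionMessage(e)))
    members[[i]] <- invert_transform(pred, params, "nearest")
  }
  set <- prediction_set(members)
  list(set = set, vote = majority_vote(set))
}
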