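#' Voxel-wise entropy uncertainty
#'
#' For each voxel, the empirical frequencies of the labels observed across
#' the N members of a prediction set are turned into the entropy
#' `H = -sum_m p_m ln p_m` (natural logarithm, `0 ln 0 := 0`).  H is zero
#' exactly where all members agree and at most `ln(M)` for `M` distinct
#' labels; for Monte-Carlo test-time augmentation it estimates voxel-wise
#' aleatoric uncertainty.
#'
#' By default the entropy is computed over the member labels as given; the
#' cascade produces binary per-structure predictions, so the usual use is one
#' entropy map per hierarchical structure (see [structure_entropy_maps()]).
#'
#' @param set a [prediction_set()].
#' @return object of class `uncertainty_map`: list with `H` (3D array, nats)
#'   and `N`.
#' @export
voxel_entropy <- function(set) {
  if (!inherits(set, "prediction_set") || set$N < 1)
    aniso_stop("input", "voxel_entropy needs a nonempty prediction set")
  labs <- sort(unique(unlist(lapply(set$members, function(m) unique(as.vector(m))))))
  H <- array(0, dim = set$shape)
  for (l in labs) {
    cnt <- Reduce(`+`, lapply(set$members, function(m) (m == l) + 0))
    p <- cnt / set$N
    nz <- p > 0
    H[nz] <- H[nz] - p[nz] * log(p[nz])
  }
  structure(list(H = H, N = set$N), class = "uncertainty_map")
}

#' @rdname voxel_entropy
#' @details `structure_entropy_maps()` projects hierarchical label members
#'   onto the three binary structures and returns one entropy map per
#'   structure.
#' @export
structure_entropy_maps <- function(set) {
  stopifnot(inherits(set, "prediction_set"))
  out <- list()
  for (s in STRUCTURES) {
    codes <- switch(s, whole = c(1, 2, 4), core = c(1, 4), enhancing = 4)
    proj <- prediction_set(lapply(set$members, function(m)
      array(as.integer(m %in% codes), dim = set$shape)))
    out[[s]] <- voxel_entropy(proj)
  }
  out
}

#' Structure volumes across a prediction set
#'
#' The volume of the segmented structure in each member, in mm^3 (positive
#' voxel count times the voxel volume).
#'
#' @param set a [prediction_set()].
#' @param structure `"whole"`, `"core"`, or `"enhancing"`; ignored for binary
#'   members, which are counted directly.
#' @param spacing voxel spacing in mm.
#' @return numeric vector of length N.
#' @export
structure_volumes <- function(set, structure = STRUCTURES, spacing = c(1, 1, 1)) {
  structure <- match.arg(structure)
  stopifnot(inherits(set, "prediction_set"))
  voxvol <- prod(spacing)
  codes <- switch(structure, whole = c(1, 2, 4), core = c(1, 4), enhancing = 4)
  vapply(set$members, function(m) {
    if (all(m %in% c(0, 1))) sum(m) * voxvol else sum(m %in% codes) * voxvol
  }, numeric(1))
}

#' Volume variation coefficient
#'
#' Structure-wise uncertainty: the standard deviation of the N structure
#' volumes divided by their mean.  The population (divide-by-N) standard
#' deviation is used by default, matching the variation-coefficient
#' convention; `sample = TRUE` switches to the divide-by-(N-1) estimate.
#' Dimensionless, hence invariant to the volume unit.
#'
#' @param V numeric vector of structure volumes.
#' @param sample use the sample standard deviation.
#' @return scalar VVC; an undefined-structure error if the mean volume is 0,
#'   so callers can report the structure as absent.
#' @export
vvc <- function(V, sample = FALSE) {
  mu <- mean(V)
  if (mu <= 0)
    aniso_stop("undefined_structure",
               "volume variation coefficient undefined: mean volume is zero")
  sig <- if (sample) sd(V) else sqrt(mean((V - mu)^2))
  sig / mu
}

#' Structure-wise uncertainty summary
#'
#' @param set a [prediction_set()].
#' @inheritParams structure_volumes
#' @return list with `volumes`, `mu`, `sigma`, `vvc` for one structure.
#' @export
structure_uncertainty <- function(set, structure = STRUCTURES,
                                  spacing = c(1, 1, 1), sample = FALSE) {
  structure <- match.arg(structure)
  V <- structure_volumes(set, structure, spacing)
  mu <- mean(V)
  if (mu <= 0)
    aniso_stop("undefined_structure", "structure %s absent in all members",
               structure)
  sig <- if (sample) sd(V) else sqrt(mean((V - mu)^2))
  list(structure = structure, volumes = V, mu = mu, sigma = sig,
       vvc = sig / mu)
}

#' Segmentation error versus structure-wise uncertainty
#'
#' For each case of a cohort, runs test-time augmentation, and tabulates the
#' segmentation error of the voted result (1 - Dice against ground truth)
#' together with the volume variation coefficient of each structure across
#' the prediction set — the desk-scale analogue of relating structure-wise
#' uncertainty to segmentation error.  Structures absent in both the
#' prediction set and the truth are skipped with a note.
#'
#' @param cases list of cases (`list(volume=, labels=)`).
#' @param predictor function mapping a [multimodal_volume()] to hierarchical
#'   labels (passed to [tta_predict()]).
#' @param N Monte-Carlo draws per case.
#' @param noise_std intensity-noise prior standard deviation.
#' @return `data.frame` with columns `case`, `structure`, `dice`,
#'   `one_minus_dice`, `mu`, `sigma`, `vvc`, plus an attribute
#'   `spearman`: the per-structure rank correlation between VVC and 1-Dice.
#' @export
error_vs_vvc_table <- function(cases, predictor, N = 20, noise_std = 0.05) {
  rows <- list()
  for (i in seq_along(cases)) {
    case <- cases[[i]]
    tta <- tta_predict(case$volume, predictor, N = N, noise_std = noise_std)
    for (s in STRUCTURES) {
      truth <- labels_to_task_mask(case$labels, s)
      pred_mask <- labels_to_task_mask(label_volume(tta$vote), s)
      su <- tryCatch(structure_uncertainty(tta$set, s), error = function(e) NULL)
      if (is.null(su) && sum(truth$mask) == 0) {
        message(sprintf("case %d: structure %s absent in prediction and truth; skipped",
                        i, s))
        next
      }
      d <- dice_score(pred_mask, truth)
      rows[[length(rows) + 1]] <- data.frame(
        case = i, structure = s, dice = d, one_minus_dice = 1 - d,
        mu = if (is.null(su)) 0 else su$mu,
        sigma = if (is.null(su)) 0 else su$sigma,
        vvc = if (is.null(su)) NA_real_ else su$vvc)
    }
  }
  tab <- do.call(rbind, rows)
  sp <- vapply(STRUCTURES, function(s) {
    sub <- tab[tab$structure == s & !is.na(tab$vvc), ]
    if (nrow(sub) < 3) return(NA_real_)
    cor(sub$vvc, sub$one_minus_dice, method = "spearman")
  }, numeric(1))
  attr(tab, "spearman") <- sp
  tab
}
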