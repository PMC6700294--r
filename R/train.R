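#' Training configuration
#'
#' Defaults follow the full-scale recipe: Dice loss, Adam with learning rate
#' 1e-3 and weight decay 1e-7, batch size 5, 30k iterations, training patch
#' extents 144x144x19 (WNet), 96x96x19 (TNet), 64x64x19 (ENet), Monte-Carlo
#' simulation number N = 20, and training-time augmentation on.  The
#' full-scale recipe is cluster-tier; [tiny_train_config()] scales it to the
#' phantom benchmark the test suite runs.
#'
#' @param patch_extent named list of 3-vectors per structure.
#' @param batch_size samples per iteration.
#' @param learning_rate,weight_decay,iterations Adam hyperparameters.
#' @param N_tta Monte-Carlo simulation count at test time.
#' @param augment apply training-time augmentation.
#' @param fg_bias fraction of patches centered on a target-positive voxel.
#' @param margin ground-truth crop margin for the downstream stages.
#' @param seed training seed.
#' @export
train_config <- function(patch_extent = list(whole = c(144L, 144L, 19L),
                                             core = c(96L, 96L, 19L),
                                             enhancing = c(64L, 64L, 19L)),
                         batch_size = 5L, learning_rate = 1e-3,
                         weight_decay = 1e-7, iterations = 30000L,
                         N_tta = 20L, augment = TRUE, fg_bias = 0.5,
                         margin = c(5L, 5L, 3L), seed = 1L) {
  if (batch_size < 1) aniso_stop("config", "batch_size must be >= 1")
  if (any(unlist(patch_extent) < 1)) aniso_stop("config", "patch extents must be positive")
  structure(list(patch_extent = patch_extent, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 iterations = as.integer(iterations), N_tta = as.integer(N_tta),
                 augment = augment, fg_bias = fg_bias,
                 margin = as.integer(margin), seed = as.integer(seed)),
            class = "train_config")
}

#' @rdname train_config
#' @param ... overrides passed to [train_config()].
#' @export
tiny_train_config <- function(...) {
  base <- train_config(patch_extent = list(whole = c(32L, 32L, 11L),
                                           core = c(24L, 24L, 11L),
                                           enhancing = c(16L, 16L, 11L)),
                       batch_size = 3L, iterations = 300L)
  modifyList(base, list(...))
}

stage_structure <- function(stage) {
  switch(stage, W = "whole", T = "core", E = "enhancing",
         whole = "whole", core = "core", enhancing = "enhancing",
         aniso_stop("config", "unknown stage %s", stage))
}

#' Sample one training patch
#'
#' Draws a `(input, target)` patch pair for one stage.  The downstream
#' stages (core, enhancing) sample inside the margin-expanded ground-truth
#' bounding box of their upstream structure, mirroring the cascade's crops.
#' With probability `fg_bias` the patch is centered on a random
#' target-positive voxel, otherwise uniformly; cases smaller than the patch
#' are zero-padded.  When `config$augment` is on, the augmentation transform
#' and intensity noise are applied to the whole case first (the same
#' operations used for test-time augmentation).
#'
#' @param case list with `volume` (normalized) and `labels`.
#' @param stage `"whole"`/`"core"`/`"enhancing"` (or `"W"`/`"T"`/`"E"`).
#' @param config a [train_config()].
#' @return list with `x` (4D input patch) and `y` (binary 3D target patch).
#' @export
sample_training_patch <- function(case, stage, config = train_config()) {
  structure_ <- stage_structure(stage)
  vol <- case$volume; lab <- case$labels
  if (config$augment) {
    params <- sample_transform()
    aug <- augment_case(vol, params, lab)
    vol <- aug$volume; lab <- aug$labels
  }
  upstream <- switch(structure_, whole = NULL, core = "whole", enhancing = "core")
  if (!is.null(upstream)) {
    box <- mask_bounding_box(labels_to_task_mask(lab, upstream), config$margin)
    if (!is.null(box)) {
      vol <- crop_box(vol, box)
      lab <- label_volume(crop_box(lab$labels, box), spacing = lab$spacing)
    }
  }
  target <- labels_to_task_mask(lab, structure_)$mask
  x <- stack_channels(vol)
  pe <- rep_len(as.integer(config$patch_extent[[structure_]]), 3L)
  d <- dim(target)
  fg <- which(target > 0, arr.ind = TRUE)
  center <- if (nrow(fg) > 0 && runif(1) < config$fg_bias) {
    fg[sample.int(nrow(fg), 1L), ]
  } else {
    c(sample.int(d[1], 1L), sample.int(d[2], 1L), sample.int(d[3], 1L))
  }
  lo <- as.integer(center) - pe %/% 2L
  lo <- pmin(pmax(lo, 1L), pmax(d - pe + 1L, 1L))
  xs <- array(0, dim = c(pe, 4L)); ys <- array(0L, dim = pe)
  take <- lapply(1:3, function(ax) lo[ax]:min(lo[ax] + pe[ax] - 1L, d[ax]))
  put <- lapply(take, function(ix) seq_along(ix))
  xs[put[[1]], put[[2]], put[[3]], ] <- x[take[[1]], take[[2]], take[[3]], , drop = FALSE]
  ys[put[[1]], put[[2]], put[[3]]] <- target[take[[1]], take[[2]], take[[3]]]
  list(x = xs, y = ys)
}

init_adam <- function(params) {
  lapply(params, function(p) if (is.null(p)) NULL
         else lapply(p, function(w) list(m = w * 0, v = w * 0)))
}

adam_update <- function(params, grads, state, lr, wd, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(params)) {
    if (is.null(params[[i]]) || is.null(grads[[i]])) next
    for (nm in names(params[[i]])) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      if (nm == "W" && wd > 0) g <- g + wd * params[[i]][[nm]]
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[i]][[nm]] <- params[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(params = params, state = state)
}

# map parameter-gradient name lists from net_backward onto the Adam layout
grad_names <- function(pg) pg

#' Train one cascade stage
#'
#' First-order adaptive-moment (Adam) optimization of the soft Dice loss on
#' foreground-biased patches.  One model is trained per (stage, view) pair;
#' the view's axis permutation is applied to every patch so the network's
#' large receptive field lies in that view's plane.
#'
#' @param blueprint a [make_blueprint()] blueprint for the stage.
#' @param view `"axial"`, `"sagittal"` or `"coronal"`.
#' @param cases list of cases (`volume` NOT yet normalized is accepted;
#'   normalization is applied here once per case).
#' @param config a [train_config()].
#' @param stage structure trained (defaults to the blueprint's natural
#'   stage: WNet-whole, TNet-core, ENet-enhancing).
#' @param log_every record the running loss every this many iterations.
#' @return object of class `trained_stage`: the realized network plus
#'   metadata and the loss log.
#' @export
train_stage <- function(blueprint, view = "axial", cases,
                        config = train_config(), stage = NULL,
                        log_every = 10L) {
  stage <- stage %||% switch(blueprint$variant, WNet = "whole", TNet = "core",
                             ENet = "enhancing", "whole")
  structure_ <- stage_structure(stage)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, match(structure_, STRUCTURES) * 100L +
                         match(view, names(VIEW_PERMS))))
  cases <- lapply(cases, function(cs)
    list(volume = normalize_case(cs$volume), labels = cs$labels))
  net <- realize(blueprint, seed = derive_seed(config$seed, 7L))
  state <- init_adam(net$params)
  log <- data.frame(iteration = integer(0), loss = numeric(0))
  run_loss <- 0; run_n <- 0
  for (it in seq_len(config$iterations)) {
    grads <- NULL; loss_acc <- 0
    for (bi in seq_len(config$batch_size)) {
      cs <- cases[[sample.int(length(cases), 1L)]]
      patch <- sample_training_patch(cs, structure_, config)
      xp <- permute_view(patch$x, view)
      yp <- permute_view(patch$y, view)
      fw <- net_forward(net, xp, keep_cache = TRUE)
      prob <- softmax_channels(fw$out)
      pfg <- prob[, , , 2]
      loss <- dice_loss(pfg, yp)
      loss_acc <- loss_acc + loss
      gp <- dice_loss_grad(pfg, yp)
      gz <- gp * pfg * (1 - pfg)
      gout <- array(0, dim = dim(fw$out))
      gout[, , , 1] <- -gz; gout[, , , 2] <- gz
      bw <- net_backward(net, fw, gout)
      grads <- if (is.null(grads)) bw$pgrads
        else mapply(function(a, g) {
          if (is.null(a)) return(g)
          mapply(`+`, a, g, SIMPLIFY = FALSE)
        }, grads, bw$pgrads, SIMPLIFY = FALSE)
    }
    loss_acc <- loss_acc / config$batch_size
    if (!is.finite(loss_acc))
      aniso_stop("training", "loss diverged (non-finite) at iteration %d", it)
    grads <- lapply(grads, function(g)
      if (is.null(g)) NULL else lapply(g, function(w) w / config$batch_size))
    upd <- adam_update(net$params, grads, state, config$learning_rate,
                       config$weight_decay, it)
    net$params <- upd$params; state <- upd$state
    run_loss <- run_loss + loss_acc; run_n <- run_n + 1
    if (it %% log_every == 0 || it == config$iterations) {
      log <- rbind(log, data.frame(iteration = it, loss = run_loss / run_n))
      run_loss <- 0; run_n <- 0
    }
  }
  structure(list(net = net, stage = structure_, view = view,
                 variant = blueprint$variant, seed = config$seed, log = log),
            class = "trained_stage")
}

#' @export
print.trained_stage <- function(x, ...) {
  cat(sprintf("<trained_stage %s/%s view=%s> final loss %.4f\n", x$variant,
              x$stage, x$view, tail(x$log$loss, 1)))
  invisible(x)
}

#' Train a full cascade
#'
#' Trains one network per stage (optionally per view) and returns stage
#' predictors ready for [run_cascade()].
#'
#' @param cases training cases.
#' @param config a [train_config()].
#' @param variant_by_stage blueprint variant per structure; defaults to
#'   WNet/TNet/ENet (use `"tiny"` everywhere for the desk-scale benchmark).
#' @param views views to train (predictions are fused when more than one).
#' @param C0 optional channel-width override.
#' @return named list of stage predictor functions, with the trained stages
#'   in attribute `"stages"`.
#' @export
train_cascade <- function(cases, config = tiny_train_config(),
                          variant_by_stage = c(whole = "tiny", core = "tiny",
                                               enhancing = "tiny"),
                          views = "axial", C0 = NULL) {
  stages <- list()
  predictors <- list()
  for (s in STRUCTURES) {
    bp <- make_blueprint(variant_by_stage[[s]], C0 = C0)
    nets <- list()
    for (v in views) {
      ts <- train_stage(bp, v, cases, config, stage = s)
      stages[[paste(s, v, sep = "_")]] <- ts
      nets[[v]] <- ts$net
    }
    predictors[[s]] <- if (length(views) == 1L) {
      net <- nets[[views]]
      vw <- views
      local({
        net_ <- net; vw_ <- vw
        function(volume) {
          x <- if (inherits(volume, "multimodal_volume")) stack_channels(volume)
               else volume
          xp <- permute_view(x, vw_)
          permute_view(net_predict(net_, xp), vw_, inverse = TRUE)
        }
      })
    } else {
      local({
        nets_ <- nets
        function(volume) {
          x <- if (inherits(volume, "multimodal_volume")) stack_channels(volume)
               else volume
          multiview_predict(x, lapply(nets_, function(n)
            function(xp) net_predict(n, xp)))
        }
      })
    }
  }
  attr(predictors, "stages") <- stages
  predictors
}

#' Evaluate hierarchical segmentations
#'
#' Per-case, per-structure Dice (and optionally Hausdorff) table.
#'
#' @param predictions list of [label_volume()]s (or 3D label arrays).
#' @param truths list of ground-truth [label_volume()]s.
#' @param hausdorff also compute the 95th-percentile Hausdorff distance
#'   (skipped for empty masks).
#' @return `data.frame` with columns `case`, `structure`, `dice`
#'   (and `hd95`).
#' @export
evaluate_segmentations <- function(predictions, truths, hausdorff = FALSE) {
  rows <- list()
  for (i in seq_along(predictions)) {
    pred <- predictions[[i]]
    if (!inherits(pred, "label_volume")) pred <- label_volume(pred)
    for (s in STRUCTURES) {
      pm <- labels_to_task_mask(pred, s)
      tm <- labels_to_task_mask(truths[[i]], s)
      row <- data.frame(case = i, structure = s, dice = dice_score(pm, tm))
      if (hausdorff) {
        row$hd95 <- tryCatch(hausdorff_distance(pm, tm, percentile = 95),
                             error = function(e) NA_real_)
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}
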