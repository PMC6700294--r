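#' Construct a multi-modal volume
#'
#' Bundles the four co-registered, skull-stripped MR channels (FLAIR, T1,
#' T1ce, T2) of one case.  All channels must share one shape and contain only
#' finite values; zeros are interpreted as stripped background.
#'
#' @param channels named list of four 3D numeric arrays, names
#'   `c("FLAIR","T1","T1ce","T2")`.
#' @param spacing voxel spacing in mm per axis (default isotropic 1 mm).
#' @return an object of class `multimodal_volume` with fields `channels`,
#'   `spacing` and `shape`.
#' @export
multimodal_volume <- function(channels, spacing = c(1, 1, 1)) {
  if (!setequal(names(channels), MODALITIES))
    aniso_stop("format", "channels must be named %s", paste(MODALITIES, collapse = ", "))
  channels <- lapply(channels[MODALITIES], as_vol3d)
  shp <- dim(channels[[1]])
  for (m in MODALITIES) {
    if (!identical(dim(channels[[m]]), shp))
      aniso_stop("format", "channel %s shape differs from FLAIR", m)
    if (!all(is.finite(channels[[m]])))
      aniso_stop("format", "channel %s contains non-finite values", m)
  }
  structure(list(channels = channels, spacing = as.numeric(spacing), shape = shp),
            class = "multimodal_volume")
}

#' Construct a label volume
#'
#' Integer segmentation with the BraTS code convention: 0 background,
#' 1 necrotic/non-enhancing core, 2 edema, 4 enhancing core.
#'
#' @param labels 3D integer array with values in \{0, 1, 2, 4\}.
#' @param spacing voxel spacing in mm per axis.
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1)) {
  labels <- as_vol3d(labels)
  bad <- setdiff(unique(as.vector(labels)), LABEL_CODES)
  if (length(bad) > 0)
    aniso_stop("format", "label volume contains codes outside {0,1,2,4}: %s",
               paste(bad, collapse = ", "))
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = as.numeric(spacing), shape = dim(labels)),
            class = "label_volume")
}

#' @export
print.multimodal_volume <- function(x, ...) {
  cat("<multimodal_volume> ", paste(x$shape, collapse = "x"),
      " voxels, spacing ", paste(x$spacing, collapse = "x"), " mm\n", sep = "")
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  tab <- table(factor(as.vector(x$labels), levels = LABEL_CODES))
  cat("<label_volume> ", paste(x$shape, collapse = "x"), " voxels; counts: ",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "), "\n", sep = "")
  invisible(x)
}

default_suffix_map <- function() {
  setNames(paste0("_", tolower(c("flair", "t1", "t1ce", "t2")), ".nii.gz"), MODALITIES)
}

#' Load a BraTS-layout case directory
#'
#' Expects `<case>/<case>_<modality>.nii.gz` (suffix map configurable) plus an
#' optional `<case>_seg.nii.gz` label image.
#'
#' @param case_path directory of one case.
#' @param suffix_map named character vector mapping modality to file suffix.
#' @param seg_suffix suffix of the optional segmentation file.
#' @return list with `volume` (a [multimodal_volume()]) and `labels` (a
#'   [label_volume()] or `NULL`).
#' @export
load_case <- function(case_path, suffix_map = default_suffix_map(),
                      seg_suffix = "_seg.nii.gz") {
  if (!dir.exists(case_path))
    aniso_stop("missing_input", "case directory not found: %s", case_path)
  id <- basename(normalizePath(case_path, mustWork = FALSE))
  channels <- list()
  for (m in MODALITIES) {
    f <- file.path(case_path, paste0(id, suffix_map[[m]]))
    if (!file.exists(f)) {
      # fall back to uncompressed
      f2 <- sub("\\.gz$", "", f)
      if (file.exists(f2)) f <- f2
      else aniso_stop("missing_input", "missing modality %s (expected %s)", m, f)
    }
    img <- RNifti::readNifti(f)
    channels[[m]] <- as_vol3d(as.array(img))
  }
  spacing <- tryCatch(RNifti::pixdim(RNifti::readNifti(
    file.path(case_path, paste0(id, suffix_map[["FLAIR"]])))),
    error = function(e) c(1, 1, 1))
  vol <- multimodal_volume(channels, spacing = spacing[seq_len(3)])
  labels <- NULL
  segf <- file.path(case_path, paste0(id, seg_suffix))
  if (!file.exists(segf)) segf <- sub("\\.gz$", "", segf)
  if (file.exists(segf)) {
    lab <- as_vol3d(as.array(RNifti::readNifti(segf)))
    if (!identical(dim(lab), vol$shape))
      aniso_stop("format", "segmentation shape differs from image channels")
    labels <- label_volume(lab, spacing = vol$spacing)
  }
  list(volume = vol, labels = labels)
}

#' Write a case in BraTS directory layout
#'
#' @param volume a [multimodal_volume()].
#' @param labels optional [label_volume()].
#' @param case_path target directory (created; its basename is the case id).
#' @inheritParams load_case
#' @return `case_path`, invisibly.
#' @export
write_case <- function(volume, labels = NULL, case_path,
                       suffix_map = default_suffix_map(),
                       seg_suffix = "_seg.nii.gz") {
  dir.create(case_path, recursive = TRUE, showWarnings = FALSE)
  id <- basename(normalizePath(case_path, mustWork = FALSE))
  for (m in MODALITIES) {
    img <- RNifti::asNifti(volume$channels[[m]], pixdim = volume$spacing)
    RNifti::writeNifti(img, file.path(case_path, paste0(id, suffix_map[[m]])))
  }
  if (!is.null(labels)) {
    img <- RNifti::asNifti(labels$labels, pixdim = labels$spacing)
    RNifti::writeNifti(img, file.path(case_path, paste0(id, seg_suffix)))
  }
  invisible(case_path)
}

#' Normalize case intensities
#'
#' Standardizes each modality to zero mean and unit standard deviation.  By
#' default the statistics are computed over the nonzero (brain) region only,
#' because skull-stripped background zeros would otherwise dominate them;
#' background voxels stay exactly zero.  The standard deviation is the
#' population (divide-by-n) value.
#'
#' @param volume a [multimodal_volume()].
#' @param region `"nonzero"` (default) or `"all"`.
#' @return a normalized [multimodal_volume()].
#' @export
normalize_case <- function(volume, region = c("nonzero", "all")) {
  region <- match.arg(region)
  out <- volume
  for (m in MODALITIES) {
    ch <- volume$channels[[m]]
    fg <- if (region == "nonzero") ch != 0 else rep(TRUE, length(ch))
    vals <- ch[fg]
    if (length(vals) == 0)
      aniso_stop("degenerate_input", "modality %s has empty foreground", m)
    mu <- mean(vals)
    sig <- sqrt(mean((vals - mu)^2))
    if (sig <= 0)
      aniso_stop("degenerate_input",
                 "modality %s has zero intensity spread over its foreground", m)
    chn <- ch
    chn[fg] <- (vals - mu) / sig
    if (region == "nonzero") chn[!fg] <- 0
    out$channels[[m]] <- chn
  }
  out
}

#' Project hierarchical labels onto one binary task mask
#'
#' whole = codes \{1,2,4\}, core = \{1,4\}, enhancing = \{4\}.
#'
#' @param labels a [label_volume()].
#' @param task one of `"whole"`, `"core"`, `"enhancing"`.
#' @return a `task_mask` object (binary 3D array plus task name).
#' @export
labels_to_task_mask <- function(labels, task = STRUCTURES) {
  task <- match.arg(task)
  codes <- switch(task, whole = c(1L, 2L, 4L), core = c(1L, 4L), enhancing = 4L)
  task_mask(array(as.integer(labels$labels %in% codes), dim = labels$shape), task,
            spacing = labels$spacing)
}

#' @rdname labels_to_task_mask
#' @param mask binary 3D array.
#' @param spacing voxel spacing in mm.
#' @export
task_mask <- function(mask, task = STRUCTURES, spacing = c(1, 1, 1)) {
  task <- match.arg(task)
  mask <- as_vol3d(mask)
  if (!all(mask %in% c(0, 1)))
    aniso_stop("format", "task mask must be binary")
  storage.mode(mask) <- "integer"
  structure(list(task = task, mask = mask, spacing = as.numeric(spacing),
                 shape = dim(mask)),
            class = "task_mask")
}

#' Recombine binary task masks into a hierarchical label volume
#'
#' Nesting is enforced by crisp-mask intersection before mapping (core is
#' clipped to whole, enhancing to the clipped core), mirroring the cascade's
#' masking semantics; the result re-projected to task masks always satisfies
#' enhancing \eqn{\subseteq} core \eqn{\subseteq} whole.
#'
#' @param whole,core,enh `task_mask` objects (or binary arrays) of one shape.
#' @param spacing voxel spacing in mm.
#' @return a [label_volume()].
#' @export
masks_to_labels <- function(whole, core, enh, spacing = NULL) {
  get_mask <- function(x) if (inherits(x, "task_mask")) x$mask else as_vol3d(x)
  w <- get_mask(whole); co <- get_mask(core); e <- get_mask(enh)
  stopifnot_same_shape(w, co, "whole/core masks")
  stopifnot_same_shape(w, e, "whole/enhancing masks")
  if (is.null(spacing))
    spacing <- if (inherits(whole, "task_mask")) whole$spacing else c(1, 1, 1)
  co <- co * w          # crisp mask: core inside whole
  e <- e * co           # enhancing inside core
  lab <- array(0L, dim = dim(w))
  lab[w == 1] <- 2L     # edema: whole minus core
  lab[co == 1] <- 1L    # non-enhancing core: core minus enhancing
  lab[e == 1] <- 4L
  label_volume(lab, spacing = spacing)
}
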