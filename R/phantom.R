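#' Specification of a synthetic multi-modal phantom
#'
#' The phantom emulates the geometry and modality contrast of skull-stripped
#' glioma MRI: a large "brain" ellipsoid of nonzero tissue inside a zero
#' background, and three nested tumor ellipsoids (whole tumor containing
#' tumor core containing enhancing core) mapped to label codes 2/1/4.
#' FLAIR and T2 are elevated over the whole-tumor region, T1ce over the
#' enhancing region (with a milder core offset on T1/T1ce), matching the
#' qualitative contrast of the real modalities.  Additive i.i.d. Gaussian
#' noise is applied per modality.
#'
#' @param shape voxel extents per axis.
#' @param center tumor centroid in voxels (0-based).
#' @param radii_whole,radii_core,radii_enh per-axis ellipsoid semi-axes in
#'   voxels; must be componentwise nested.  `radii_enh` of all zeros makes an
#'   LGG-like case without enhancing core.
#' @param contrast named list per modality with entries `base`, `whole`,
#'   `core`, `enh` (additive intensity offsets; nested regions accumulate).
#' @param noise_std additive Gaussian noise standard deviation.
#' @param deform_sd standard deviation in voxels of an optional smooth random
#'   boundary deformation (0 disables it).
#' @param seed integer seed making the case deterministic.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48, 48, 28),
                         center = (shape - 1) / 2,
                         radii_whole = c(10, 9, 7),
                         radii_core = c(6, 6, 5),
                         radii_enh = c(3, 3, 3),
                         contrast = default_phantom_contrast(),
                         noise_std = 8,
                         deform_sd = 0,
                         seed = 1L) {
  if (noise_std < 0) aniso_stop("spec", "noise_std must be nonnegative")
  if (any(radii_enh > radii_core) || any(radii_core > radii_whole))
    aniso_stop("spec", "ellipsoid radii must be nested: enh <= core <= whole")
  if (any(center - radii_whole < 0) || any(center + radii_whole > shape - 1))
    aniso_stop("spec", "whole-tumor ellipsoid does not fit inside the grid")
  structure(list(shape = as.integer(shape), center = as.numeric(center),
                 radii_whole = as.numeric(radii_whole),
                 radii_core = as.numeric(radii_core),
                 radii_enh = as.numeric(radii_enh),
                 contrast = contrast, noise_std = noise_std,
                 deform_sd = deform_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_phantom_contrast <- function() {
  list(FLAIR = c(base = 80,  whole = 50,  core = 5,   enh = 0),
       T1    = c(base = 100, whole = -10, core = -15, enh = 5),
       T1ce  = c(base = 100, whole = -5,  core = 10,  enh = 60),
       T2    = c(base = 90,  whole = 45,  core = -10, enh = 5))
}

# Signed ellipsoid field: <=1 inside.  An optional smooth random radial
# perturbation makes the boundary non-analytic for harder tests.
ellipsoid_field <- function(shape, center, radii, deform = NULL) {
  x <- (seq_len(shape[1]) - 1 - center[1])
  y <- (seq_len(shape[2]) - 1 - center[2])
  z <- (seq_len(shape[3]) - 1 - center[3])
  fx <- (x / radii[1])^2
  fy <- (y / radii[2])^2
  fz <- (z / radii[3])^2
  f <- outer(outer(fx, fy, `+`), fz, `+`)
  if (!is.null(deform)) f <- f + deform
  f
}

smooth_noise_field <- function(shape, sd) {
  f <- array(rnorm(prod(shape)), dim = shape)
  # separable moving-average smoothing, three passes
  for (i in 1:3) {
    f <- (f +
      f[c(1, seq_len(shape[1] - 1)), , , drop = FALSE] +
      f[c(seq_len(shape[1] - 1) + 1, shape[1]), , , drop = FALSE]) / 3
    f <- (f +
      f[, c(1, seq_len(shape[2] - 1)), , drop = FALSE] +
      f[, c(seq_len(shape[2] - 1) + 1, shape[2]), , drop = FALSE]) / 3
    f <- (f +
      f[, , c(1, seq_len(shape[3] - 1)), drop = FALSE] +
      f[, , c(seq_len(shape[3] - 1) + 1, shape[3]), drop = FALSE]) / 3
  }
  f * sd / max(stats::sd(as.vector(f)), 1e-12)
}

#' Generate one phantom case
#'
#' Deterministic given `spec$seed`.  With `noise_std = 0` the channels are
#' piecewise constant.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` ([multimodal_volume()]) and `labels`
#'   ([label_volume()]).
#' @export
generate_case <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  shp <- spec$shape
  deform <- if (spec$deform_sd > 0)
    smooth_noise_field(shp, spec$deform_sd * 0.1) else NULL
  brain_r <- pmax((shp - 1) / 2 - 1, spec$radii_whole + 1)
  brain <- ellipsoid_field(shp, (shp - 1) / 2, brain_r) <= 1
  whole <- ellipsoid_field(shp, spec$center, spec$radii_whole, deform) <= 1
  core  <- ellipsoid_field(shp, spec$center, spec$radii_core, deform) <= 1
  enh <- if (all(spec$radii_enh > 0))
    ellipsoid_field(shp, spec$center, spec$radii_enh, deform) <= 1
  else array(FALSE, dim = shp)
  core <- core & whole; enh <- enh & core
  lab <- array(0L, dim = shp)
  lab[whole] <- 2L; lab[core] <- 1L; lab[enh] <- 4L
  channels <- list()
  for (m in MODALITIES) {
    co <- spec$contrast[[m]]
    ch <- array(0, dim = shp)
    ch[brain] <- co[["base"]]
    ch[whole] <- ch[whole] + co[["whole"]]
    ch[core]  <- ch[core] + co[["core"]]
    ch[enh]   <- ch[enh] + co[["enh"]]
    if (spec$noise_std > 0)
      ch[brain] <- ch[brain] + rnorm(sum(brain), 0, spec$noise_std)
    channels[[m]] <- ch
  }
  list(volume = multimodal_volume(channels),
       labels = label_volume(lab))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a reproducible phantom cohort
#'
#' Randomizes tumor center, radii and contrast around `base_spec`, with a
#' configurable fraction of LGG-like cases whose enhancing region is empty
#' (exercising the empty-target path of the third cascade stage).
#'
#' @param n number of cases.
#' @param base_spec a [phantom_spec()] providing the nominal geometry.
#' @param seed root seed; case i uses a seed derived from it.
#' @param lgg_fraction fraction of cases generated without enhancing core.
#' @param center_jitter max per-axis center displacement (voxels).
#' @param radii_range multiplicative range for the tumor radii.
#' @param contrast_range multiplicative range for the tumor contrast offsets.
#' @return list of cases as returned by [generate_case()]; each carries its
#'   `spec` as an attribute.
#' @export
generate_cohort <- function(n, base_spec = phantom_spec(), seed = 1L,
                            lgg_fraction = 0.25,
                            center_jitter = 3,
                            radii_range = c(0.75, 1.15),
                            contrast_range = c(0.8, 1.2)) {
  if (n < 1) aniso_stop("spec", "n must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 0L))
  lgg <- runif(n) < lgg_fraction
  out <- vector("list", n)
  for (i in seq_len(n)) {
    jit <- runif(3, -center_jitter, center_jitter)
    rs <- runif(1, radii_range[1], radii_range[2])
    cs <- runif(1, contrast_range[1], contrast_range[2])
    contrast <- lapply(base_spec$contrast, function(v) {
      v[c("whole", "core", "enh")] <- v[c("whole", "core", "enh")] * cs
      v
    })
    shp <- base_spec$shape
    rw <- pmax(base_spec$radii_whole * rs, 3)
    center <- pmin(pmax(base_spec$center + jit, rw + 1), shp - 2 - rw)
    spec <- phantom_spec(shape = shp, center = center,
                         radii_whole = rw,
                         radii_core = pmax(base_spec$radii_core * rs, 2),
                         radii_enh = if (lgg[i]) c(0, 0, 0)
                                     else pmax(base_spec$radii_enh * rs, 1.5),
                         contrast = contrast,
                         noise_std = base_spec$noise_std,
                         deform_sd = base_spec$deform_sd,
                         seed = derive_seed(seed, i))
    case <- generate_case(spec)
    attr(case, "spec") <- spec
    out[[i]] <- case
  }
  out
}
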