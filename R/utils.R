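#' Modalities and hierarchical structures
#'
#' BraTS-style cases carry four co-registered MR channels and three nested
#' binary target structures: enhancing core inside tumor core inside whole
#' tumor.
#' @name conventions
#' @keywords internal
NULL

MODALITIES <- c("FLAIR", "T1", "T1ce", "T2")
STRUCTURES <- c("whole", "core", "enhancing")
LABEL_CODES <- c(0L, 1L, 2L, 4L)  # background, necrotic/non-enh core, edema, enhancing

# Deterministic fan-out of one root seed into per-task streams.  Keeps every
# derived seed a valid 32-bit integer.
derive_seed <- function(root, index) {
  as.integer((as.double(root) * 48271 + as.double(index) * 9973) %% 2147483647)
}

as_vol3d <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- c(length(x), 1L, 1L)
  if (length(d) == 2L) d <- c(d, 1L)
  # rebuild to shed foreign classes/attributes (e.g. NIfTI image handles)
  array(as.double(x), dim = d)
}

stopifnot_same_shape <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    aniso_stop("format", "shape mismatch between %s: %s vs %s", what,
               paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  invisible(TRUE)
}
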