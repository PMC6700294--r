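#' @useDynLib anisoseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd quantile cor setNames
#' @importFrom utils write.table read.table modifyList
NULL

# Classed conditions so callers (and tests) can distinguish failure modes.
aniso_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("anisoseg_", class), "anisoseg_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
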