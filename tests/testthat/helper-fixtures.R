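# Shared fixtures, all generated in code.

small_spec <- function(noise_std = 8, seed = 1L, radii_enh = c(2.5, 2.5, 2), ...) {
  phantom_spec(shape = c(40, 40, 24), radii_whole = c(9, 8, 6),
               radii_core = c(5, 5, 4), radii_enh = radii_enh,
               noise_std = noise_std, seed = seed, ...)
}

small_case <- function(...) generate_case(small_spec(...))

# Memoised tiny-cascade training shared across test files (trained once per
# test run under a fixed seed).
.trained_env <- new.env(parent = emptyenv())

trained_tiny_cascade <- function() {
  if (is.null(.trained_env$preds)) {
    cohort <- generate_cohort(20, phantom_spec(), seed = 11)
    cfg <- tiny_train_config(iterations = 150, batch_size = 3, seed = 5)
    .trained_env$preds <- train_cascade(cohort, cfg)
  }
  .trained_env$preds
}

normalized_cases <- function(cases) {
  lapply(cases, function(cs)
    list(volume = normalize_case(cs$volume), labels = cs$labels))
}

# Predictor wrapper injecting label-space noise proportional to a corruption
# level (random rotation/scale jitter of the predicted labels per draw).
corrupted_predictor <- function(base, kappa) {
  function(volume) {
    lab <- base(volume)
    jit <- identity_transform()
    jit$r <- stats::rnorm(3, 0, kappa)
    jit$s <- exp(stats::rnorm(1, 0, kappa / 2))
    apply_transform(lab, jit, "nearest")
  }
}
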