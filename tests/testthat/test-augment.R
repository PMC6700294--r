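test_that("sampled transform parameters follow the stated priors", {
  set.seed(1)
  n <- 1e4
  draws <- replicate(n, sample_transform(), simplify = FALSE)
  flips <- t(vapply(draws, function(p) p$f, logical(3)))
  expect_true(all(colMeans(flips) > 0.45 & colMeans(flips) < 0.55))
  s <- vapply(draws, function(p) p$s, numeric(1))
  expect_gte(min(s), 0.8); expect_lte(max(s), 1.2)
  expect_lt(abs(mean(s) - 1.0), 0.01)
  r <- t(vapply(draws, function(p) p$r, numeric(3)))
  expect_gte(min(r), 0); expect_lt(max(r), 2 * pi)
  expect_lt(max(abs(colMeans(r) - pi)), 0.1)
  # same seed, same sequence
  set.seed(7); a <- replicate(5, sample_transform(), simplify = FALSE)
  set.seed(7); b <- replicate(5, sample_transform(), simplify = FALSE)
  expect_identical(a, b)
})

test_that("identity parameters leave volumes unchanged", {
  cs <- small_case()
  out <- apply_transform(cs$volume, identity_transform(), "linear")
  expect_equal(out$channels$FLAIR, cs$volume$channels$FLAIR, tolerance = 1e-10)
  lab <- apply_transform(cs$labels, identity_transform())
  expect_identical(lab$labels, cs$labels$labels)
})

test_that("flips are exactly involutive", {
  # off-center tumor so a single flip visibly moves the labels
  cs <- generate_case(small_spec(center = c(17, 21, 10)))
  for (ax in 1:3) {
    p <- identity_transform(); p$f[ax] <- TRUE
    once <- apply_transform(cs$labels, p)
    twice <- apply_transform(once, p)
    expect_identical(twice$labels, cs$labels$labels)
    expect_false(identical(once$labels, cs$labels$labels))
  }
})

test_that("an in-plane quarter rotation conserves label counts within 2%", {
  cs <- small_case()
  p <- identity_transform(); p$r[3] <- pi / 2
  rot <- apply_transform(cs$labels, p)
  for (code in c(1L, 2L, 4L)) {
    n0 <- sum(cs$labels$labels == code)
    n1 <- sum(rot$labels == code)
    expect_lt(abs(n1 - n0) / n0, 0.02)
  }
})

test_that("invert_transform undoes apply_transform up to interpolation loss", {
  cs <- generate_case(phantom_spec())
  wm <- labels_to_task_mask(cs$labels, "whole")
  set.seed(11)
  ds <- replicate(25, {
    p <- sample_transform()
    dice_score(invert_transform(apply_transform(wm, p), p), wm)
  })
  expect_gte(mean(ds), 0.95)
  expect_gte(min(ds), 0.90)
  expect_error(invert_transform(wm, local({q <- identity_transform(); q$s <- 0; q})),
               class = "anisoseg_transform")
  expect_error(apply_transform(wm, local({q <- identity_transform(); q$r[1] <- NaN; q})),
               class = "anisoseg_transform")
})

test_that("intensity noise has the configured scale and is seed-reproducible", {
  cs <- small_case()
  vol <- normalize_case(cs$volume)
  set.seed(5)
  noisy <- add_noise(vol, 0.05)
  delta <- noisy$channels$FLAIR - vol$channels$FLAIR
  n <- length(delta)
  expect_lt(abs(mean(delta)), 3 * 0.05 / sqrt(n))
  expect_gt(sd(delta), 0.045); expect_lt(sd(delta), 0.055)
  set.seed(5)
  noisy2 <- add_noise(vol, 0.05)
  expect_identical(noisy$channels, noisy2$channels)
})

test_that("tta with identity transforms and N=1 equals plain prediction", {
  cs <- small_case()
  vol <- normalize_case(cs$volume)
  pred <- function(v) labels_to_task_mask(cs$labels, "whole")$mask
  set.seed(1)
  out <- tta_predict(vol, pred, N = 1, noise_std = 0, identity_transforms = TRUE)
  expect_identical(array(out$vote, dim = vol$shape), pred(vol))
})

test_that("a deterministic constant predictor yields identical members and vote", {
  cs <- small_case()
  vol <- normalize_case(cs$volume)
  const <- labels_to_task_mask(cs$labels, "core")$mask
  set.seed(2)
  out <- tta_predict(vol, function(v) const, N = 4, noise_std = 0,
                     identity_transforms = TRUE)
  for (m in out$set$members) expect_true(all(m == const))
  expect_true(all(out$vote == const))
})

test_that("majority voting follows the modal label with ties toward foreground", {
  mk <- function(vals) lapply(vals, function(v) array(v, dim = c(1, 1, 1)))
  expect_equal(as.vector(majority_vote(prediction_set(mk(c(1, 1, 0))))), 1L)
  expect_equal(as.vector(majority_vote(prediction_set(mk(c(0, 0, 1))))), 0L)
  # 10 vs 10 tie at N = 20 goes to foreground
  expect_equal(as.vector(majority_vote(prediction_set(mk(rep(c(0, 1), 10))))), 1L)
  expect_equal(as.vector(majority_vote(prediction_set(mk(rep(c(0, 1), 10))),
                                       tie = "background")), 0L)
})

test_that("voting is member-order invariant and votes only observed labels", {
  set.seed(3)
  members <- lapply(1:7, function(i)
    array(sample(c(0L, 1L, 2L, 4L), 60, replace = TRUE), dim = c(5, 4, 3)))
  v1 <- majority_vote(prediction_set(members))
  v2 <- majority_vote(prediction_set(members[sample(7)]))
  expect_identical(v1, v2)
  expect_true(all(v1 %in% c(0L, 1L, 2L, 4L)))
})

test_that("training augmentation shares the test-time augmentation code path", {
  cs <- small_case()
  vol <- normalize_case(cs$volume)
  cfg <- tiny_train_config(augment = TRUE, fg_bias = 0)
  set.seed(31)
  patch <- sample_training_patch(list(volume = vol, labels = cs$labels),
                                 "whole", cfg)
  # replay the same RNG stream through the augmentation operations directly
  set.seed(31)
  params <- sample_transform()
  aug <- anisoseg:::augment_case(vol, params, cs$labels)
  target <- labels_to_task_mask(aug$labels, "whole")$mask
  d <- dim(target)
  invisible(runif(1))  # the sampler's foreground-bias draw
  center <- c(sample.int(d[1], 1L), sample.int(d[2], 1L), sample.int(d[3], 1L))
  pe <- cfg$patch_extent$whole
  lo <- pmin(pmax(center - pe %/% 2L, 1L), pmax(d - pe + 1L, 1L))
  expect_equal(patch$y[1, 1, 1], target[lo[1], lo[2], lo[3]])
  expect_equal(patch$x[1, 1, 1, 1],
               stack_channels(aug$volume)[lo[1], lo[2], lo[3], 1])
})
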