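test_that("the uncertainty gate resets exactly the voxels above threshold", {
  d <- c(4, 4, 2)
  pfg <- array(0.9, dim = d)
  H <- array(0, dim = d)
  H[1, 1, 1] <- 0.5    # above threshold
  H[2, 1, 1] <- 0.1    # below
  H[3, 1, 1] <- 0.2    # exactly at threshold: strict inequality, unchanged
  g <- uncertainty_gate(pfg, H, 0.2)
  expect_equal(g[1, 1, 1, 2], 0.5); expect_equal(g[1, 1, 1, 1], 0.5)
  expect_equal(g[2, 1, 1, 2], 0.9)
  expect_equal(g[3, 1, 1, 2], 0.9)
  expect_equal(sum(g[, , , 2] == 0.5), 1)
  expect_error(uncertainty_gate(pfg, array(0, dim = c(3, 3, 3))),
               class = "anisoseg_format")
})

test_that("gating is idempotent", {
  set.seed(6)
  d <- c(5, 5, 3)
  pfg <- array(runif(prod(d)), dim = d)
  H <- array(runif(prod(d), 0, 0.7), dim = d)
  g1 <- uncertainty_gate(pfg, H, 0.2)
  g2 <- uncertainty_gate(g1, H, 0.2)
  expect_identical(g1, g2)
})

test_that("zero pairwise weights reduce refinement to the unary argmax bit-exactly", {
  set.seed(7)
  d <- c(6, 5, 3)
  pfg <- array(runif(prod(d)), dim = d)
  img <- array(rnorm(prod(d)), dim = d)
  m <- crf_refine(pfg, img, crf_params(spatial_weight = 0, appearance_weight = 0))
  expect_identical(m$mask, array((pfg >= 0.5) + 0L, dim = d))
})

test_that("unanimous 0/1 probabilities on a uniform image are left unchanged", {
  d <- c(6, 6, 1)
  pfg <- array(0, dim = d); pfg[3:4, 3:4, 1] <- 1
  img <- array(0, dim = d)
  m <- crf_refine(pfg, img, crf_params(spatial_weight = 0.5,
                                       appearance_weight = 0,
                                       iterations = 5))
  expect_identical(m$mask, array(as.integer(pfg), dim = d))
})

test_that("a strong spatial kernel relabels an isolated flipped voxel", {
  d <- c(3, 3, 1)
  pfg <- array(0.1, dim = d); pfg[2, 2, 1] <- 0.6
  img <- array(0, dim = d)
  pars <- crf_params(spatial_weight = 3, spatial_sigma = 1.5,
                     appearance_weight = 0, iterations = 5, radius = 3)
  m <- crf_refine(pfg, img, pars)
  expect_equal(m$mask[2, 2, 1], 0L)
  # and the mean-field labeling attains the enumeration optimum here
  best <- Inf; best_lab <- NULL
  for (k in 0:(2^prod(d) - 1)) {
    lab <- array(as.integer(intToBits(k)[1:prod(d)]), dim = d)
    e <- crf_labeling_energy(lab, pfg, img, pars)
    if (e < best) { best <- e; best_lab <- lab }
  }
  expect_identical(m$mask, best_lab)
})

test_that("mean-field energy is within 5% of the exhaustive minimum on tiny instances", {
  set.seed(12)
  for (trial in 1:6) {
    d <- c(3, 2, 2)  # 12 voxels
    pfg <- array(runif(prod(d), 0.05, 0.95), dim = d)
    img <- array(rnorm(prod(d)), dim = d)
    pars <- crf_params(spatial_weight = runif(1, 0.2, 0.8),
                       spatial_sigma = 1.2,
                       appearance_weight = runif(1, 0.2, 0.8),
                       appearance_sigma_spatial = 2,
                       appearance_sigma_intensity = 0.8,
                       iterations = 10, radius = 4)
    m <- crf_refine(pfg, img, pars)
    e_mf <- crf_labeling_energy(m$mask, pfg, img, pars)
    e_min <- Inf
    for (k in 0:(2^prod(d) - 1)) {
      lab <- array(as.integer(intToBits(k)[1:prod(d)]), dim = d)
      e_min <- min(e_min, crf_labeling_energy(lab, pfg, img, pars))
    }
    expect_lte(e_mf, e_min * 1.05 + 1e-9)
  }
})

test_that("an infinite threshold or zero entropy reduces the gated CRF to the naive one", {
  set.seed(13)
  d <- c(8, 8, 2)
  pfg <- array(runif(prod(d)), dim = d)
  img <- array(rnorm(prod(d)), dim = d)
  H <- array(runif(prod(d), 0, 1), dim = d)
  naive <- crf_refine(pfg, img, crf_params())
  g_inf <- uncertainty_aware_crf(pfg, H, img, crf_params(theta = Inf))
  expect_identical(g_inf$mask, naive$mask)
  g_h0 <- uncertainty_aware_crf(pfg, array(0, dim = d), img, crf_params())
  expect_identical(g_h0$mask, naive$mask)
})

test_that("gating frees a confidently mis-segmented high-entropy region for recovery", {
  set.seed(4)
  d <- c(20, 20, 1)
  img <- array(-1, dim = d); img[11:20, , ] <- 1
  img <- img + array(rnorm(prod(d), 0, 0.1), dim = d)
  truth <- array(0L, dim = d); truth[11:20, , ] <- 1L
  pfg <- array(0.05, dim = d); pfg[11:20, , ] <- 0.9
  pfg[13:17, 8:12, 1] <- 1e-5   # confidently wrong block
  H <- array(0, dim = d); H[13:17, 8:12, 1] <- 0.5
  pars <- crf_params(appearance_weight = 0.3, spatial_weight = 0.5)
  naive <- crf_refine(pfg, img, pars)
  gated <- uncertainty_aware_crf(pfg, H, img, pars)
  wrong_naive <- sum(naive$mask != truth)
  wrong_gated <- sum(gated$mask != truth)
  expect_lte(wrong_gated, wrong_naive)
  expect_gt(wrong_naive, 0)     # the naive CRF cannot overcome the unaries
  expect_equal(wrong_gated, 0L) # the gated one recovers the block
})

test_that("cascade post-processing keeps the label hierarchy", {
  cs <- small_case()
  vol <- normalize_case(cs$volume)
  out <- run_cascade(vol, oracle_stage_predictors(cs$labels, vol))
  set <- prediction_set(replicate(3, cs$labels$labels, simplify = FALSE))
  emaps <- structure_entropy_maps(set)
  post <- postprocess_cascade(out, emaps, vol,
                              crf_params(iterations = 2, radius = 2))
  w <- labels_to_task_mask(post, "whole")$mask
  co <- labels_to_task_mask(post, "core")$mask
  e <- labels_to_task_mask(post, "enhancing")$mask
  expect_true(all(e <= co) && all(co <= w))
})
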