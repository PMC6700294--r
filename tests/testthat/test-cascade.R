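test_that("bounding boxes are tight, half-open, margin-expanded and clipped", {
  m <- array(0L, dim = c(10, 10, 10)); m[6, 7, 8] <- 1L
  bb <- mask_bounding_box(m, 0)
  expect_equal(bb$lo, c(5L, 6L, 7L)); expect_equal(bb$hi, c(6L, 7L, 8L))
  expect_null(mask_bounding_box(array(0L, dim = c(4, 4, 4))))
  m2 <- array(0L, dim = c(10, 10, 10)); m2[1, 1, 1] <- 1L; m2[10, 10, 10] <- 1L
  bb2 <- mask_bounding_box(m2, 2)
  expect_equal(bb2$lo, c(0L, 0L, 0L)); expect_equal(bb2$hi, c(10L, 10L, 10L))
})

test_that("multi-view fusion averages the per-view softmax outputs", {
  d <- c(6, 6, 6)
  mkpred <- function(p) function(x) {
    out <- array(0, dim = c(dim(x)[1:3], 2))
    out[, , , 1] <- 1 - p; out[, , , 2] <- p
    out
  }
  x <- array(rnorm(prod(d) * 4), dim = c(d, 4))
  fused <- multiview_predict(x, list(axial = mkpred(0.6), sagittal = mkpred(0.7),
                                     coronal = mkpred(0.8)))
  expect_equal(unique(round(as.vector(fused[, , , 2]), 10)), 0.7)
  expect_error(multiview_predict(x, list(axial = mkpred(0.5))),
               class = "anisoseg_config")
})

test_that("view permutation round-trips are the identity", {
  x <- array(rnorm(5 * 6 * 7 * 2), dim = c(5, 6, 7, 2))
  for (v in c("axial", "sagittal", "coronal")) {
    expect_identical(permute_view(permute_view(x, v), v, inverse = TRUE), x)
    expect_identical(permute_view(permute_view(x[, , , 1], v), v, inverse = TRUE),
                     x[, , , 1])
  }
})

test_that("identical predictors across views equal the single-view output on symmetric input", {
  d <- c(6, 6, 6)
  x <- array(rnorm(prod(d)), dim = d)
  x <- (x + aperm(x, c(2, 3, 1)) + aperm(x, c(3, 1, 2))) / 3  # cyclic-symmetric
  x4 <- array(rep(x, 4), dim = c(d, 4))
  pred <- function(xp) {
    out <- array(0, dim = c(dim(xp)[1:3], 2))
    p <- 1 / (1 + exp(-xp[, , , 1]))
    out[, , , 1] <- 1 - p; out[, , , 2] <- p
    out
  }
  fused <- multiview_predict(x4, list(axial = pred, sagittal = pred, coronal = pred))
  expect_equal(fused, pred(x4), tolerance = 1e-12)
})

test_that("sliding-window inference covers every voxel and averages overlaps", {
  d <- c(8, 8, 4)
  x <- array(rnorm(prod(d) * 4), dim = c(d, 4))
  # constant predictor: stride must not matter
  const <- function(p) {
    out <- array(0, dim = c(dim(p)[1:3], 2))
    out[, , , 1] <- 0.3; out[, , , 2] <- 0.7
    out
  }
  o1 <- sliding_window_infer(x, const, c(4, 4, 4), c(2, 2, 2))
  expect_equal(unique(as.vector(o1[, , , 2])), 0.7)
  expect_equal(dim(o1)[1:3], d)
  # volume smaller than patch: single padded patch, shape preserved
  o2 <- sliding_window_infer(x, const, c(16, 16, 8))
  expect_equal(dim(o2)[1:3], d)
  expect_error(sliding_window_infer(x, const, c(4, 4, 4), c(5, 5, 5)),
               class = "anisoseg_config")
})

test_that("half-stride overlap equals the mean of the two covering patch outputs", {
  # predictor output depends on the patch content, so overlap averaging shows
  nx <- 12; patch <- c(8, 12, 4); stride <- c(4, 12, 4)
  x <- array(rnorm(nx * 12 * 4 * 4), dim = c(nx, 12, 4, 4))
  pred <- function(p) {
    out <- array(0, dim = c(dim(p)[1:3], 2))
    v <- mean(p)  # patch-dependent constant field
    out[, , , 1] <- 1 - v; out[, , , 2] <- v
    out
  }
  o <- sliding_window_infer(x, pred, patch, stride)
  p1 <- mean(x[1:8, , , ]); p2 <- mean(x[5:12, , , ])
  # voxels 5..8 are covered by both patches
  expect_equal(unique(round(as.vector(o[5:8, , , 2]), 12)),
               round((p1 + p2) / 2, 12))
  expect_equal(unique(round(as.vector(o[1:4, , , 2]), 12)), round(p1, 12))
})

test_that("the cascade with oracle stage predictors recovers the ground truth exactly", {
  for (lgg in c(FALSE, TRUE)) {
    cs <- generate_case(small_spec(seed = 3 + lgg,
                                   radii_enh = if (lgg) c(0, 0, 0) else c(2.5, 2.5, 2)))
    vol <- normalize_case(cs$volume)
    out <- run_cascade(vol, oracle_stage_predictors(cs$labels, vol))
    expect_identical(out$labels$labels, cs$labels$labels)
  }
})

test_that("an empty first stage short-circuits the downstream networks", {
  cs <- small_case()
  vol <- normalize_case(cs$volume)
  calls <- new.env(); calls$core <- 0L; calls$enh <- 0L
  empty_pred <- function(v) {
    out <- array(0, dim = c(v$shape, 2)); out[, , , 1] <- 1
    out
  }
  preds <- list(
    whole = empty_pred,
    core = function(v) { calls$core <- calls$core + 1L; empty_pred(v) },
    enhancing = function(v) { calls$enh <- calls$enh + 1L; empty_pred(v) })
  out <- run_cascade(vol, preds)
  expect_true(all(out$labels$labels == 0L))
  expect_equal(calls$core, 0L)
  expect_equal(calls$enh, 0L)
})

test_that("crisp masking removes downstream positives outside their parent mask", {
  cs <- small_case()
  vol <- normalize_case(cs$volume)
  oracle <- oracle_stage_predictors(cs$labels, vol)
  everywhere <- function(v) {
    d <- if (inherits(v, "multimodal_volume")) v$shape else dim(v)[1:3]
    out <- array(0, dim = c(d, 2)); out[, , , 2] <- 1
    out
  }
  preds <- list(whole = oracle$whole, core = everywhere, enhancing = everywhere)
  out <- run_cascade(vol, preds)
  whole_truth <- labels_to_task_mask(cs$labels, "whole")$mask
  core_pred <- labels_to_task_mask(out$labels, "core")$mask
  expect_true(all(core_pred <= whole_truth))
  # no voxel outside the stage-1 bounding box carries a nonzero label
  bb <- mask_bounding_box(whole_truth, c(5L, 5L, 3L))
  outside <- array(TRUE, dim = vol$shape)
  outside[(bb$lo[1] + 1):bb$hi[1], (bb$lo[2] + 1):bb$hi[2],
          (bb$lo[3] + 1):bb$hi[3]] <- FALSE
  expect_true(all(out$labels$labels[outside] == 0L))
})

test_that("cascade outputs satisfy the nesting invariant on a whole cohort", {
  cohort <- generate_cohort(6, small_spec(), seed = 14)
  rand_pred <- function(v) {
    d <- if (inherits(v, "multimodal_volume")) v$shape else dim(v)[1:3]
    p <- array(runif(prod(d)), dim = d)
    out <- array(0, dim = c(d, 2))
    out[, , , 1] <- 1 - p; out[, , , 2] <- p
    out
  }
  set.seed(15)
  for (cs in cohort) {
    vol <- normalize_case(cs$volume)
    out <- run_cascade(vol, list(whole = rand_pred, core = rand_pred,
                                 enhancing = rand_pred))
    w <- labels_to_task_mask(out$labels, "whole")$mask
    co <- labels_to_task_mask(out$labels, "core")$mask
    e <- labels_to_task_mask(out$labels, "enhancing")$mask
    expect_true(all(e <= co) && all(co <= w))
  }
})
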