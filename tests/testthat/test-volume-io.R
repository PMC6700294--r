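test_that("a case written in BraTS layout reloads with identical grids", {
  cs <- small_case(noise_std = 5)
  dir <- file.path(tempdir(), "case_rt")
  on.exit(unlink(dir, recursive = TRUE))
  write_case(cs$volume, cs$labels, dir)
  back <- load_case(dir)
  for (m in c("FLAIR", "T1", "T1ce", "T2"))
    expect_equal(back$volume$channels[[m]], cs$volume$channels[[m]],
                 tolerance = 1e-6)
  expect_identical(back$labels$labels, cs$labels$labels)
})

test_that("a directory lacking one modality raises a missing-input error naming it", {
  cs <- small_case()
  dir <- file.path(tempdir(), "case_miss")
  on.exit(unlink(dir, recursive = TRUE))
  write_case(cs$volume, NULL, dir)
  unlink(file.path(dir, paste0(basename(dir), "_t1ce.nii.gz")))
  expect_error(load_case(dir), "T1ce", class = "anisoseg_missing_input")
})

test_that("label volumes reject codes outside the BraTS alphabet", {
  expect_error(label_volume(array(c(0L, 3L), dim = c(2, 1, 1))),
               class = "anisoseg_format")
  cs <- small_case()
  dir <- file.path(tempdir(), "case_badseg")
  on.exit(unlink(dir, recursive = TRUE))
  write_case(cs$volume, NULL, dir)
  bad <- array(3L, dim = cs$volume$shape)
  RNifti::writeNifti(RNifti::asNifti(bad),
                     file.path(dir, paste0(basename(dir), "_seg.nii.gz")))
  expect_error(load_case(dir), class = "anisoseg_format")
})

test_that("normalization standardizes each modality over the brain region", {
  cs <- small_case(noise_std = 6)
  norm <- normalize_case(cs$volume)
  for (m in c("FLAIR", "T1", "T1ce", "T2")) {
    fg <- cs$volume$channels[[m]] != 0
    vals <- norm$channels[[m]][fg]
    expect_lt(abs(mean(vals)), 1e-6)
    expect_lt(abs(sqrt(mean((vals - mean(vals))^2)) - 1), 1e-6)
    expect_true(all(norm$channels[[m]][!fg] == 0))
  }
})

test_that("foreground values {1,2,3} z-score to +-1.2247, 0 under population std", {
  ch <- array(0, dim = c(3, 1, 1)); ch[] <- c(1, 2, 3)
  vol <- multimodal_volume(list(FLAIR = ch, T1 = ch, T1ce = ch, T2 = ch))
  norm <- normalize_case(vol)
  expect_equal(as.vector(norm$channels$FLAIR),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
})

test_that("constant-valued foreground is rejected as degenerate", {
  ch <- array(5, dim = c(4, 4, 2))
  vol <- multimodal_volume(list(FLAIR = ch, T1 = ch, T1ce = ch, T2 = ch))
  expect_error(normalize_case(vol), class = "anisoseg_degenerate_input")
})

test_that("label codes project onto the hierarchical task masks", {
  lab <- label_volume(array(c(0L, 2L, 1L, 4L), dim = c(4, 1, 1)))
  expect_equal(as.vector(labels_to_task_mask(lab, "whole")$mask), c(0, 1, 1, 1))
  expect_equal(as.vector(labels_to_task_mask(lab, "core")$mask), c(0, 0, 1, 1))
  expect_equal(as.vector(labels_to_task_mask(lab, "enhancing")$mask), c(0, 0, 0, 1))
})

test_that("masks_to_labels maps nested masks to codes and enforces nesting", {
  w <- array(c(1L, 1L, 1L), dim = c(3, 1, 1))
  co <- array(c(0L, 1L, 1L), dim = c(3, 1, 1))
  e <- array(c(0L, 0L, 1L), dim = c(3, 1, 1))
  lab <- masks_to_labels(w, co, e)
  expect_equal(as.vector(lab$labels), c(2L, 1L, 4L))
  # core voxel outside whole is masked away
  w2 <- array(c(0L, 1L), dim = c(2, 1, 1))
  co2 <- array(c(1L, 1L), dim = c(2, 1, 1))
  e2 <- array(0L, dim = c(2, 1, 1))
  expect_equal(as.vector(masks_to_labels(w2, co2, e2)$labels), c(0L, 1L))
  # all-zero masks give all-zero labels
  z <- array(0L, dim = c(2, 2, 2))
  expect_true(all(masks_to_labels(z, z, z)$labels == 0L))
  # shape mismatch is a format error
  expect_error(masks_to_labels(w, co2, e), class = "anisoseg_format")
})

test_that("mask projection and recombination are mutually inverse on any label volume", {
  set.seed(42)
  for (i in 1:10) {
    lab <- label_volume(array(sample(c(0L, 1L, 2L, 4L), 5 * 4 * 3, replace = TRUE),
                              dim = c(5, 4, 3)))
    masks <- lapply(c("whole", "core", "enhancing"),
                    function(s) labels_to_task_mask(lab, s))
    back <- masks_to_labels(masks[[1]], masks[[2]], masks[[3]])
    expect_identical(back$labels, lab$labels)
    # re-projection always nests
    w <- labels_to_task_mask(back, "whole")$mask
    co <- labels_to_task_mask(back, "core")$mask
    e <- labels_to_task_mask(back, "enhancing")$mask
    expect_true(all(e <= co) && all(co <= w))
  }
})
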