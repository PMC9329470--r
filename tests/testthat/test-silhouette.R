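test_that("merging a single series at target spacing is the identity", {
  arr <- array(runif(10 * 8 * 8), c(10, 8, 8))
  sp <- c(3.0, 2.232, 2.232)
  out <- merge_series(list(list(voxels = arr, z_offset_mm = 0, spacing = sp)),
                      target_spacing = sp)
  expect_identical(out$voxels, arr)
})

test_that("series merging stacks, de-duplicates, and detects gaps", {
  sp <- c(3.0, 2.232, 2.232)
  s1 <- array(1, c(10, 6, 6))
  s2 <- array(2, c(10, 6, 6))
  out <- merge_series(list(list(voxels = s1, z_offset_mm = 0, spacing = sp),
                           list(voxels = s2, z_offset_mm = 10 * 3, spacing = sp)),
                      target_spacing = sp)
  expect_equal(dim(out$voxels)[1], 20)
  # overlap of 3 slices, keep_first keeps the earlier series values
  out2 <- merge_series(list(list(voxels = s1, z_offset_mm = 0, spacing = sp),
                            list(voxels = s2, z_offset_mm = 7 * 3, spacing = sp)),
                       dedup = "keep_first", target_spacing = sp)
  expect_equal(dim(out2$voxels)[1], 10 + 10 - 3)
  expect_true(all(out2$voxels[8:10, , ] == 1))
  expect_true(all(out2$voxels[11:17, , ] == 2))
  out3 <- merge_series(list(list(voxels = s1, z_offset_mm = 0, spacing = sp),
                            list(voxels = s2, z_offset_mm = 7 * 3, spacing = sp)),
                       dedup = "mean", target_spacing = sp)
  expect_true(all(out3$voxels[8:10, , ] == 1.5))
  expect_error(
    merge_series(list(list(voxels = s1, z_offset_mm = 0, spacing = sp),
                      list(voxels = s2, z_offset_mm = 13 * 3, spacing = sp)),
                 target_spacing = sp),
    "non-contiguous")
})

test_that("axial segmentation recovers shapes and applies its rules", {
  truth <- ellipse_slice(80, 90, 30, 25)
  expect_identical(segment_axial(truth * 1.0), truth)
  # noisy case: SNR 10 (signal 1, noise sd 0.1)
  noisy <- truth + withr::with_seed(1, rnorm(length(truth), 0, 0.1))
  seg <- segment_axial(noisy)
  dice <- 2 * sum(seg & truth) / (sum(seg) + sum(truth))
  expect_gte(dice, 0.98)
  # largest-component rule: 500 px blob retained, 20 px blob dropped
  two <- matrix(0, 60, 60)
  two[10:29, 10:34] <- 1   # 500 px
  two[45:48, 45:49] <- 1   # 20 px
  seg2 <- segment_axial(two)
  expect_equal(sum(seg2), 500)
  expect_equal(sum(seg2[45:48, 45:49]), 0)
  expect_error(segment_axial(matrix(c(1, NA, 0, 0), 2)), "nonfinite")
  expect_identical(segment_axial(matrix(5, 4, 4)), matrix(0L, 4, 4))
})

test_that("projection matches the per-ray any() oracle", {
  v <- array(0L, c(3, 3, 3))
  v[2, 1, 0 + 1] <- 1L
  cor <- project(v, "coronal")
  expect_equal(sum(cor), 1)
  expect_equal(cor[2, 1], 1L)
  expect_true(all(project(array(1L, c(4, 4, 4)), "sagittal") == 1L))
  expect_error(project(array(2L, c(2, 2, 2))), "non-binary")
  withr::with_seed(4, for (rep in 1:10) {
    d <- sample(2:6, 3, replace = TRUE)
    vol <- array(rbinom(prod(d), 1, 0.3), d)
    cor <- project(vol, "coronal")
    sag <- project(vol, "sagittal")
    for (z in seq_len(d[1])) for (x in seq_len(d[3]))
      expect_equal(cor[z, x], as.integer(any(vol[z, , x] == 1)))
    for (z in seq_len(d[1])) for (y in seq_len(d[2]))
      expect_equal(sag[z, y], as.integer(any(vol[z, y, ] == 1)))
  })
})

test_that("projection of a one-slice projection is idempotent", {
  img <- ellipse_slice(20, 30, 10, 6)
  vol <- array(img, c(nrow(img), ncol(img), 1))
  expect_identical(project(vol, "sagittal"), img)
})

test_that("aspect correction rescales to isotropic pixels", {
  img <- ellipse_slice(100, 50, 20, 40)
  expect_identical(aspect_correct(img, c(2.232, 2.232)), img)
  out <- aspect_correct(img, c(3.0, 2.232))
  expect_equal(nrow(out), round(100 * 3.0 / 2.232))
  expect_equal(ncol(out), 50)
  rimg <- withr::with_seed(2, matrix(rbinom(5000, 1, 0.4), 100, 50))
  expect_true(all(aspect_correct(rimg, c(3.0, 2.232)) %in% c(0L, 1L)))
})

test_that("silhouette composition has the fixed two-panel layout", {
  cor <- ellipse_slice(150, 60, 25, 70)
  sag <- ellipse_slice(150, 40, 15, 70)
  sil <- compose_silhouette(cor, sag)
  expect_identical(dim(sil), c(237L, 256L))
  expect_true(all(sil %in% c(0L, 1L)))
  # left panel depends only on the coronal input
  sil2 <- compose_silhouette(cor, ellipse_slice(150, 40, 10, 50))
  expect_identical(sil[, 1:128], sil2[, 1:128])
  expect_false(identical(sil[, 129:256], sil2[, 129:256]))
  expect_error(compose_silhouette(matrix(0L, 5, 5), sag), "empty silhouette")
  # all-ones panels land as centered frames of known extent
  ones <- matrix(1L, 10, 10)
  frame <- compose_silhouette(ones, ones)
  expected <- matrix(0L, 237, 256)
  expected[55:182, 1:128] <- 1L     # 128x128 block centered vertically
  expected[55:182, 129:256] <- 1L
  expect_identical(matrix(as.integer(frame), 237, 256), expected)
})

test_that("volume-to-silhouette pipeline is deterministic and mask-faithful", {
  v <- generate_phantom(phantom_params("male"), spacing = c(6, 4.464, 4.464))
  tmp1 <- withr::local_tempfile(fileext = ".png")
  tmp2 <- withr::local_tempfile(fileext = ".png")
  volume_to_silhouette(v, out_png = tmp1)
  volume_to_silhouette(v, out_png = tmp2)
  expect_identical(readBin(tmp1, "raw", file.size(tmp1)),
                   readBin(tmp2, "raw", file.size(tmp2)))
  # binary labelled volume: segmentation recovers the body mask exactly
  vb <- body_volume(voxels = (v$labels > 0L) * 1.0, spacing = v$spacing)
  s_seg <- volume_to_silhouette(vb)
  s_lab <- volume_to_silhouette(v)
  expect_identical(matrix(as.integer(s_seg), 237, 256),
                   matrix(as.integer(s_lab), 237, 256))
  s_read <- read_silhouette(tmp1)
  expect_identical(matrix(as.integer(s_read), 237, 256),
                   matrix(as.integer(s_lab), 237, 256))
})

test_that("silhouette ignores voxel intensities interior to the body", {
  v <- generate_phantom(phantom_params("female", noise_sd = 0),
                        spacing = c(6, 4.464, 4.464), intensities = TRUE)
  s1 <- volume_to_silhouette(body_volume(voxels = v$voxels,
                                         spacing = v$spacing))
  # interior voxels: all 6-neighbours inside the body
  b <- v$labels > 0L
  d <- dim(b)
  interior <- b
  interior[] <- FALSE
  interior[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <-
    b[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] &
    b[1:(d[1] - 2), 2:(d[2] - 1), 2:(d[3] - 1)] &
    b[3:d[1], 2:(d[2] - 1), 2:(d[3] - 1)] &
    b[2:(d[1] - 1), 1:(d[2] - 2), 2:(d[3] - 1)] &
    b[2:(d[1] - 1), 3:d[2], 2:(d[3] - 1)] &
    b[2:(d[1] - 1), 2:(d[2] - 1), 1:(d[3] - 2)] &
    b[2:(d[1] - 1), 2:(d[2] - 1), 3:d[3]]
  vox <- v$voxels
  idx <- which(interior)
  vox[idx] <- withr::with_seed(8, sample(vox[idx]))
  s2 <- volume_to_silhouette(body_volume(voxels = vox, spacing = v$spacing))
  expect_identical(unclass(s1), unclass(s2))
})

test_that("a fatter phantom casts a larger silhouette shadow", {
  sp <- c(6, 4.464, 4.464)
  for (i in 1:10) {
    base <- phantom_params("male", vat_asat_shape = (i - 5) / 3,
                           height_mm = 1650 + 20 * i)
    fat <- base
    fat$size_factor <- 1.3
    s1 <- volume_to_silhouette(generate_phantom(base, spacing = sp))
    s2 <- volume_to_silhouette(generate_phantom(fat, spacing = sp))
    expect_gt(sum(s2), sum(s1))
  }
})

test_that("outline mode emits a thin boundary subset of the filled shadow", {
  v <- generate_phantom(phantom_params("male"), spacing = c(6, 4.464, 4.464))
  filled <- volume_to_silhouette(v)
  hollow <- volume_to_silhouette(v, outline = TRUE)
  expect_identical(dim(hollow), c(237L, 256L))
  expect_lt(sum(hollow), sum(filled) / 2)
})
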