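test_that("resize halves and rescales the physical pixel size", {
  ip <- intensity_plane(matrix(runif(64^2, 0, 255), 64, 64), 0.0901)
  rp <- resize_plane(ip, 16)
  expect_equal(dim(rp), c(16L, 16L))
  expect_equal(attr(rp, "pixel_size_um"), 0.0901 * 4)
  expect_error(resize_plane(matrix(0, 4, 6), 2), "square")
})

test_that("resize to the same size is the identity and constants stay constant", {
  m <- matrix(runif(32^2), 32, 32)
  expect_equal(unclass(resize_plane(m, 32)), m, ignore_attr = TRUE)
  cm <- matrix(7, 32, 32)
  expect_true(all(resize_plane(cm, 13) == 7))
  expect_true(all(resize_plane(cm, 51) == 7))
})

test_that("nearest-neighbour resize keeps masks binary; resize is idempotent", {
  msk <- matrix(0L, 40, 40); msk[5:20, 10:30] <- 1L
  r <- resize_plane(msk, 16, method = "nearest")
  expect_true(all(r %in% 0:1))
  m <- matrix(runif(40^2), 40, 40)
  once <- resize_plane(m, 16)
  expect_equal(resize_plane(once, 16), once)
})

test_that("augmentation yields exactly n_iterations x n_inputs pairs", {
  img <- matrix(runif(24^2, 0, 255), 24, 24)
  msk <- matrix(0L, 24, 24); msk[8:16, 6:18] <- 1L
  for (nit in c(0, 1, 8)) {
    aug <- augment_dataset(rep(list(img), 3), rep(list(msk), 3),
                           augment_spec(n_iterations = nit, seed = 2))
    expect_length(aug$images, nit * 3)
    expect_length(aug$masks, nit * 3)
  }
  expect_error(augment_dataset(list(img), list(msk, msk), augment_spec()),
               "same length")
})

test_that("augmented masks stay binary and share the image transform", {
  img <- matrix(runif(24^2, 0, 255), 24, 24)
  msk <- matrix(0L, 24, 24); msk[8:16, 6:18] <- 1L
  aug <- augment_dataset(list(img), list(msk),
                         augment_spec(n_iterations = 8, seed = 9))
  for (k in seq_along(aug$masks)) {
    expect_true(all(aug$masks[[k]] %in% 0:1))
    # replaying the recorded transform on the source mask reproduces it
    p <- aug$transforms[[k]]
    M <- isletpol:::affine_matrix(24, 24, p$angle_deg, p$shear, p$shift_r,
                                  p$shift_c, p$flip_h, p$flip_v)
    replay <- isletpol:::apply_affine(msk, M, "nearest")
    expect_equal(unname(replay), unname(aug$masks[[k]]), ignore_attr = TRUE)
  }
  aug2 <- augment_dataset(list(img), list(msk),
                          augment_spec(n_iterations = 8, seed = 9))
  expect_identical(aug, aug2)
})

test_that("volume stacking records the confocal anisotropy factor", {
  planes <- lapply(1:5, function(i) matrix(0L, 8, 8))
  expect_equal(round(stack_masks(planes, voxel_geometry(0.0902, 0.3362))$z_scale,
                     1), 3.7)
  expect_equal(stack_masks(planes, voxel_geometry(1, 1))$z_scale, 1)
  expect_equal(dim(stack_masks(planes)$voxels), c(5L, 8L, 8L))
  expect_error(stack_masks(list(matrix(0, 4, 4), matrix(0, 5, 5))), "shape")
  expect_error(stack_masks(list()), "at least one")
})

test_that("volumes round-trip losslessly through multi-page TIFF", {
  d <- withr::local_tempdir()
  planes <- lapply(1:4, function(i) matrix(sample(0:255, 64, TRUE), 8, 8))
  vol <- stack_masks(planes, voxel_geometry(0.0902, 0.3362))
  f <- file.path(d, "v.tif")
  export_volume(vol, f, bits = 8)
  v2 <- read_volume(f)
  expect_identical(v2$voxels, vol$voxels)
  expect_equal(v2$z_scale, vol$z_scale)
  # 16-bit label volumes too
  lab <- stack_masks(list(matrix(sample(0:999, 64, TRUE), 8, 8)))
  f2 <- file.path(d, "l.tif")
  export_volume(lab, f2, bits = 16)
  expect_identical(read_volume(f2)$voxels, lab$voxels)
  expect_error(export_volume(list(), f), "invalid")
})

test_that("plane PNG IO preserves 8-bit values", {
  d <- withr::local_tempdir()
  ip <- intensity_plane(matrix(sample(0:255, 256, TRUE), 16, 16))
  f <- file.path(d, "p.png")
  write_plane(ip, f)
  expect_equal(unclass(read_plane(f)), unclass(ip), ignore_attr = TRUE)
})
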