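test_that("largest-remainder split reproduces the 185-exam cohort sizes", {
  ids <- sprintf("ex%03d", 1:185)
  sp <- split_cohort(ids, c(0.80, 0.09, 0.11), seed = 3)
  expect_length(sp$train_ids, 148)
  expect_length(sp$tune_ids, 17)
  expect_length(sp$test_ids, 20)
})

test_that("split_cohort partitions are disjoint, exhaustive and deterministic", {
  set.seed(11)
  for (t in 1:20) {
    n <- sample(3:200, 1)
    f <- runif(3); f <- f / sum(f)
    ids <- paste0("e", seq_len(n))
    sp <- split_cohort(ids, f, seed = t)
    all_ids <- c(sp$train_ids, sp$tune_ids, sp$test_ids)
    expect_equal(sort(all_ids), sort(ids))
    expect_equal(anyDuplicated(all_ids), 0)
  }
  sp1 <- split_cohort(paste0("e", 1:50), seed = 9)
  sp2 <- split_cohort(paste0("e", 1:50), seed = 9)
  expect_identical(sp1, sp2)
  # degenerate fractions
  sp <- split_cohort(paste0("e", 1:10), c(1, 0, 0), seed = 1)
  expect_length(sp$train_ids, 10)
  expect_length(sp$tune_ids, 0)
  # invalid input
  expect_error(split_cohort(character(0)), "empty")
  expect_error(split_cohort(paste0("e", 1:10), c(0.5, 0.2, 0.2)), "summing|sum")
})

test_that("make_folds gives near-equal folds covering every exam once", {
  ids <- sprintf("ex%03d", 1:148)
  f <- make_folds(ids, k = 5, seed = 2)
  expect_equal(sort(as.numeric(table(f)), decreasing = TRUE), c(30, 30, 30, 29, 29))
  expect_setequal(names(f), ids)
  f10 <- make_folds(paste0("e", 1:10), k = 5, seed = 0)
  expect_true(all(table(f10) == 2))
  expect_error(make_folds(paste0("e", 1:3), k = 5), "exceeds")
  expect_error(make_folds(paste0("e", 1:3), k = 1), "at least 2")
})

test_that("resample_to_grid geometry: identity, scaling and padding", {
  arr <- array(runif(2 * 512 * 512), c(2, 512, 512))
  e <- exam(image_volume(arr, c(5, 0.7, 0.7), "a"),
            segmentation_mask(array(0, dim(arr)), c(5, 0.7, 0.7), "a"))
  expect_identical(resample_to_grid(e, 512), e)

  big <- array(runif(1 * 1024 * 1024), c(1, 1024, 1024))
  e2 <- exam(image_volume(big, c(5, 0.5, 0.5), "b"),
             segmentation_mask(array(0, dim(big)), c(5, 0.5, 0.5), "b"))
  r2 <- resample_to_grid(e2, 512)
  expect_equal(dim(r2$image$voxels), c(1, 512, 512))
  expect_equal(r2$image$spacing, c(5, 1, 1))

  # 640 x 512 -> scale 0.8 -> 512 x 410, padded 51/51
  rect <- array(0, c(1, 640, 512))
  rect[1, 200:400, 100:300] <- 1
  m <- array(0, dim(rect)); m[1, 250:350, 150:250] <- 1
  e3 <- exam(image_volume(rect, c(5, 1, 1), "c"),
             segmentation_mask(m, c(5, 1, 1), "c"))
  r3 <- resample_to_grid(e3, 512)
  expect_equal(dim(r3$image$voxels), c(1, 512, 512))
  # rows were the larger dimension: cols scaled to 410 and padded 51 each side
  expect_true(all(r3$image$voxels[1, , 1:51] == 0))
  expect_true(all(r3$image$voxels[1, , 462:512] == 0))
  expect_true(all(r3$mask$voxels %in% c(0, 1)))
  expect_equal(r3$image$spacing[2:3], c(1.25, 1.25))
})

test_that("resampling squares keeps masks binary and centroids in place", {
  set.seed(5)
  for (t in 1:5) {
    n <- sample(c(96L, 128L, 160L), 1)
    m <- array(0, c(1, n, n))
    r0 <- sample(10:(n / 2), 1)
    m[1, r0:(r0 + 20), r0:(r0 + 20)] <- 1
    e <- exam(image_volume(m * 100, c(5, 1, 1), "sq"),
              segmentation_mask(m, c(5, 1, 1), "sq"))
    r <- resample_to_grid(e, 64)
    expect_true(all(r$mask$voxels %in% c(0, 1)))
    s <- n / 64
    cen0 <- which(m[1, , ] == 1, arr.ind = TRUE) |> colMeans()
    cen1 <- which(r$mask$voxels[1, , ] == 1, arr.ind = TRUE) |> colMeans()
    # centroid moves by no more than one output-voxel diagonal
    expect_lt(sqrt(sum((cen0 / s - cen1)^2)), sqrt(2) + 1e-9)
  }
})

test_that("NIfTI round trip preserves voxels (float32) and spacing exactly", {
  set.seed(7)
  vox <- array(runif(4 * 32 * 24, 0, 100), c(4, 32, 24))
  msk <- array(rbinom(4 * 32 * 24, 1, 0.2), c(4, 32, 24))
  e <- exam(image_volume(vox, c(3.5, 0.8, 0.9), "rt"),
            segmentation_mask(msk, c(3.5, 0.8, 0.9), "rt"))
  td <- withr::local_tempdir()
  ip <- file.path(td, "img.nii.gz"); mp <- file.path(td, "msk.nii.gz")
  write_exam_nifti(e, ip, mp)
  back <- read_exam(ip, mp, location_label = "PLL")
  expect_equal(back$image$voxels, vox, tolerance = 1e-6)
  expect_equal(back$image$spacing, c(3.5, 0.8, 0.9), tolerance = 1e-6)
  expect_identical(back$mask$voxels, msk * 1)
  expect_equal(back$location_label, "PLL")
})

test_that("raw float32 cache round trip matches NIfTI contract", {
  vox <- array(rnorm(2 * 16 * 16), c(2, 16, 16))
  v <- image_volume(vox, c(4, 1, 1), "cache1")
  td <- withr::local_tempdir()
  write_volume_raw(v, file.path(td, "vol"))
  back <- read_volume_raw(file.path(td, "vol"))
  expect_equal(back$voxels, vox, tolerance = 1e-6)
  expect_equal(back$spacing, c(4, 1, 1))
  expect_equal(back$exam_id, "cache1")
})

test_that("read_exam rejects invalid masks and incongruent grids", {
  td <- withr::local_tempdir()
  vox <- array(runif(2 * 16 * 16), c(2, 16, 16))
  e_img <- image_volume(vox, c(4, 1, 1), "x")
  write_volume_nifti(e_img, file.path(td, "i.nii.gz"))

  bad <- array(0, c(2, 16, 16)); bad[1, 1, 1] <- 2
  write_volume_nifti(image_volume(bad, c(4, 1, 1), "m"), file.path(td, "m2.nii.gz"))
  expect_error(read_exam(file.path(td, "i.nii.gz"), file.path(td, "m2.nii.gz")),
               "outside")

  small <- array(0, c(2, 8, 8))
  write_volume_nifti(image_volume(small, c(4, 1, 1), "m"), file.path(td, "ms.nii.gz"))
  expect_error(read_exam(file.path(td, "i.nii.gz"), file.path(td, "ms.nii.gz")),
               "mismatch")

  expect_error(read_exam(file.path(td, "none.nii"), file.path(td, "ms.nii.gz")),
               "no such file")

  # valid 0/1 mask passes through unchanged
  good <- array(rbinom(2 * 16 * 16, 1, 0.4), c(2, 16, 16))
  write_volume_nifti(image_volume(good, c(4, 1, 1), "m"), file.path(td, "mg.nii.gz"))
  ex <- read_exam(file.path(td, "i.nii.gz"), file.path(td, "mg.nii.gz"))
  expect_identical(ex$mask$voxels, good * 1)
})

test_that("domain constructors enforce their invariants", {
  expect_error(image_volume(array(c(1, NA), c(1, 1, 2))), "non-finite")
  expect_error(image_volume(array(1, c(1, 2, 2)), spacing = c(0, 1, 1)), "positive")
  expect_error(segmentation_mask(array(2, c(1, 2, 2))), "0 or 1")
  img <- image_volume(array(1, c(1, 4, 4)))
  msk <- segmentation_mask(array(0, c(1, 4, 5)))
  expect_error(exam(img, msk), "differ")
  expect_error(exam(img, segmentation_mask(array(0, c(1, 4, 4))),
                    location_label = "nope"), "location_label")
})
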