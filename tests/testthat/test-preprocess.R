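vol3 <- function(x, spacing = c(1, 1, 1), id = "v") {
  image_volume(array(x, c(1, 1, length(x))), spacing, id)
}

test_that("z-score normalization: hand values, moments, affine invariance", {
  z <- normalize_zscore(vol3(c(1, 2, 3)))
  expect_equal(as.numeric(z$voxels), c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)

  set.seed(1)
  v <- image_volume(array(runif(4 * 8 * 8, 5, 50), c(4, 8, 8)))
  z2 <- normalize_zscore(v)
  expect_lt(abs(mean(z2$voxels)), 1e-6)
  expect_lt(abs(sqrt(mean(z2$voxels^2)) - 1), 1e-6)

  v_aff <- image_volume(3.7 * v$voxels + 11, v$spacing, "aff")
  expect_equal(normalize_zscore(v_aff)$voxels, z2$voxels, tolerance = 1e-6)

  expect_warning(zc <- normalize_zscore(image_volume(array(5, c(1, 2, 2)))),
                 "constant")
  expect_true(all(zc$voxels == 0))
})

test_that("min-max normalization per volume and per slice", {
  m <- normalize_minmax_volume(vol3(c(2, 4, 6)))
  expect_equal(as.numeric(m$voxels), c(0, 0.5, 1))

  set.seed(2)
  v <- image_volume(array(rnorm(3 * 6 * 6), c(3, 6, 6)))
  mv <- normalize_minmax_volume(v)
  expect_equal(range(mv$voxels), c(0, 1))

  ms <- normalize_minmax_slice(v)
  for (k in 1:3) expect_equal(range(ms$voxels[k, , ]), c(0, 1))

  # explicit per-slice independence
  two <- image_volume(array(c(0, 2, 5, 15), c(2, 1, 2)))
  # slice 1 holds (0, 5), slice 2 holds (2, 15) under (slice, row, col) order
  m2 <- normalize_minmax_slice(two)
  for (k in 1:2) expect_equal(range(m2$voxels[k, , ]), c(0, 1))

  # single-slice volume: both methods agree
  v1 <- image_volume(array(runif(36), c(1, 6, 6)))
  expect_equal(normalize_minmax_slice(v1)$voxels,
               normalize_minmax_volume(v1)$voxels)

  expect_warning(mc <- normalize_minmax_volume(image_volume(array(3, c(1, 2, 2)))),
                 "constant")
  expect_true(all(mc$voxels == 0))
})

test_that("nyul training is affine-invariant and produces increasing scales", {
  cohort <- get_cohort("nyul", phantom_config(n_exams = 4, seed = 13))
  vols <- lapply(cohort, function(e) e$image)
  sc <- nyul_train(vols)
  expect_true(all(diff(sc$standard_values) > 0))

  # identical training volumes: standard values equal each volume's mapped landmarks
  sc1 <- nyul_train(list(vols[[1]], vols[[1]], vols[[1]]))
  sc_single <- nyul_train(list(vols[[1]]))
  expect_equal(sc1$standard_values, sc_single$standard_values, tolerance = 1e-12)

  # global affine intensity change leaves the standard scale unchanged
  v_aff <- image_volume(2.5 * vols[[2]]$voxels + 7, vols[[2]]$spacing, "aff")
  expect_equal(nyul_train(list(vols[[2]]))$standard_values,
               nyul_train(list(v_aff))$standard_values, tolerance = 1e-9)

  expect_error(nyul_train(list()), "at least one")
  expect_error(nyul_scale(c(10, 5, 90), c(0, 1, 2)), "increasing")
})

test_that("nyul transform hits the standard scale and preserves ordering", {
  cohort <- get_cohort("nyul", phantom_config(n_exams = 4, seed = 13))
  vols <- lapply(cohort, function(e) e$image)
  sc <- nyul_train(vols)
  srange <- diff(range(sc$standard_values))
  for (v in vols) {
    out <- nyul_apply(v, sc)
    # monotone non-decreasing in input intensity
    ord <- order(as.numeric(v$voxels))
    expect_false(is.unsorted(as.numeric(out$voxels)[ord]))
    # transformed landmarks match the standard values within 1% of the range
    nz <- out$voxels[v$voxels != 0]
    fgv <- out$voxels[v$voxels > mean(v$voxels[v$voxels != 0])]
    lm_out <- quantile(fgv, sc$percentiles / 100, names = FALSE)
    expect_lt(max(abs(lm_out - sc$standard_values)), 0.01 * srange)
  }
  # a volume whose landmarks already sit on the scale is left unchanged
  v0 <- vols[[1]]
  out0 <- nyul_apply(v0, nyul_train(list(v0)))
  out00 <- nyul_apply(out0, nyul_train(list(out0)))
  expect_equal(out00$voxels, out0$voxels, tolerance = 1e-6)
})

test_that("nyul on a linear ramp is an exact affine rescale", {
  ramp <- image_volume(array(seq(10, 110, length.out = 512), c(2, 16, 16)))
  sc <- nyul_train(list(ramp), percentiles = c(1, 50, 99))
  out <- nyul_apply(ramp, sc)
  fit <- lm(as.numeric(out$voxels) ~ as.numeric(ramp$voxels))
  expect_lt(max(abs(residuals(fit))), 1e-8)
})

test_that("bias correction: degenerate inputs and positivity", {
  flat <- image_volume(array(7, c(2, 16, 16)))
  out <- bias_correct(flat)
  expect_equal(out$voxels / flat$voxels, array(1, dim(flat$voxels)),
               tolerance = 1e-6)
  expect_error(bias_correct(image_volume(array(0, c(2, 8, 8)))), "zero")

  cohort <- get_cohort("biaspos", phantom_config(n_exams = 2, seed = 23))
  for (e in cohort) expect_gte(min(bias_correct(e$image)$voxels), 0)
})

test_that("bias correction restores multiplicative phantoms", {
  withr::local_options(slseg.bias_cache = FALSE)
  improved <- 0
  for (i in 1:8) {
    cfg <- phantom_config(n_exams = 1, bias_amplitude = 0.3, noise_sd = 0,
                          site_styles = list(c(0, 1, 1)), seed = 300 + i)
    e <- generate_exam(cfg, 1)
    truth <- attr(e, "truth")
    c0 <- cor(as.numeric(e$image$voxels), as.numeric(truth))
    c1 <- cor(as.numeric(bias_correct(e$image)$voxels), as.numeric(truth))
    if (c1 > c0) improved <- improved + 1
  }
  expect_gte(improved, 7)
})

test_that("apply_preprocess composes correctly and never touches the mask", {
  cohort <- get_cohort("pp", phantom_config(n_exams = 2, seed = 31))
  e <- cohort[[1]]
  spec <- preprocess_spec("zscore", bias_correct = FALSE)
  out <- apply_preprocess(e, spec)
  expect_equal(out$image$voxels, normalize_zscore(e$image)$voxels)
  expect_identical(out$mask$voxels, e$mask$voxels)

  expect_error(apply_preprocess(e, preprocess_spec("nyul", bias_correct = FALSE)),
               "nyul_scale")
  expect_error(preprocess_spec("zscore", nyul_scale = nyul_scale(c(1, 50, 99), 0:2)),
               "only applies")
})

test_that("normalizations are pure per-intensity maps (voxel-order invariant)", {
  set.seed(4)
  v <- array(runif(2 * 8 * 8, 1, 9), c(2, 8, 8))
  perm <- sample(length(v))
  for (f in list(normalize_zscore, normalize_minmax_volume)) {
    a <- f(image_volume(v))$voxels
    vp <- v; vp[perm] <- v  # permuted copy of the same multiset
    b <- f(image_volume(vp))$voxels
    expect_equal(as.numeric(b[perm]), as.numeric(a), tolerance = 1e-12)
  }
})
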