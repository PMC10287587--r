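test_that("forward pass obeys shape, range and divisibility contracts", {
  for (att in c(FALSE, TRUE)) {
    net <- build_unet(unet_config(3, 4, attention = att), seed = 1)
    x <- array(rnorm(64 * 64 * 2), c(64, 64, 2, 1))
    out <- unet_forward(net, x)$out
    expect_equal(dim(out), c(64, 64, 2, 1))
    expect_true(all(out > 0 & out < 1))
  }
  net5 <- build_unet(unet_config(5, 2), seed = 1)
  expect_error(unet_forward(net5, array(0, c(40, 40, 1, 1))), "divisible")
})

test_that("attention gate coefficients stay in [0, 1] and gate the skip", {
  net <- build_unet(unet_config(3, 4, attention = TRUE), seed = 2)
  s <- array(rnorm(32 * 32 * 2 * 8), c(32, 32, 2, 8))
  g <- array(rnorm(16 * 16 * 2 * 16), c(16, 16, 2, 16))
  p <- slseg:::att_params(net$params, "dec2")
  at <- slseg:::attgate_fwd(s, g, p)
  expect_true(all(at$cache$alpha >= 0 & at$cache$alpha <= 1))
  expect_equal(dim(at$out), dim(s))
  # output is the skip scaled by the coefficients
  expect_equal(at$out[, , , 1], s[, , , 1] * at$cache$alpha[, , , 1])
})

test_that("count_parameters matches the hand count and real parameter arrays", {
  expect_identical(count_parameters(unet_config(1, 1)), 26)
  set.seed(3)
  for (t in 1:5) {
    cfg <- unet_config(sample(1:4, 1), sample(c(1, 2, 4, 8), 1),
                       attention = sample(c(TRUE, FALSE), 1))
    net <- build_unet(cfg, seed = t)
    expect_identical(count_parameters(cfg),
                     sum(vapply(net$params, length, numeric(1))))
    att_cfg <- cfg; att_cfg$attention <- TRUE
    plain_cfg <- cfg; plain_cfg$attention <- FALSE
    expect_gte(count_parameters(att_cfg), count_parameters(plain_cfg))
  }
})

test_that("dice loss: closed forms and degenerate overlaps", {
  y <- array(rbinom(200, 1, 0.4), c(10, 20))
  expect_lt(dice_loss(y, y), 1e-5)

  half <- array(rep(c(0, 1), each = 100), c(10, 20))
  expect_gte(dice_loss(1 - half, half), 0.999)

  p <- array(0.5, c(10, 20))
  expect_equal(dice_loss(p, half), 0.5, tolerance = 1e-5)

  expect_error(dice_loss(array(0, c(2, 2)), array(0, c(2, 3))), "mismatch")
})

test_that("dice loss gradient matches finite differences", {
  set.seed(8)
  p <- array(runif(64, 0.05, 0.95), c(4, 4, 4, 1))
  y <- array(rbinom(64, 1, 0.3), c(4, 4, 4, 1))
  g <- dice_loss(p, y, gradient = TRUE)
  for (i in sample(64, 6)) {
    eps <- 1e-6
    p1 <- p; p1[i] <- p1[i] + eps
    p2 <- p; p2[i] <- p2[i] - eps
    num <- (dice_loss(p1, y) - dice_loss(p2, y)) / (2 * eps)
    expect_equal(g$dpred[i], num, tolerance = 1e-5)
  }
})

test_that("network gradients match finite differences (both architectures)", {
  for (att in c(FALSE, TRUE)) {
    cfg <- unet_config(2, 2, attention = att)
    net <- build_unet(cfg, seed = 1)
    set.seed(2)
    x <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
    y <- array(rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 2, 1))
    fw <- unet_forward(net, x, training = TRUE)
    dl <- dice_loss(fw$out, y, gradient = TRUE)
    gr <- unet_backward(net, fw$cache, dl$dpred)
    loss_at <- function(params) {
      n2 <- net; n2$params <- params
      dice_loss(unet_forward(n2, x, training = TRUE)$out, y)
    }
    set.seed(3)
    for (nm in names(net$params)) {
      for (t in sample(length(net$params[[nm]]), min(2, length(net$params[[nm]])))) {
        eps <- 1e-5
        p1 <- net$params; p1[[nm]][t] <- p1[[nm]][t] + eps
        p2 <- net$params; p2[[nm]][t] <- p2[[nm]][t] - eps
        num <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
        ana <- gr[[nm]][t]
        # relative agreement, except where the true gradient vanishes (a
        # conv bias immediately followed by batch-norm has zero effect)
        agree <- abs(num - ana) / max(abs(num) + abs(ana), 1e-8) < 1e-3 ||
          abs(num) + abs(ana) < 1e-6
        expect_true(agree, label = sprintf("gradient of %s[%d]", nm, t))
      }
    }
  }
})

test_that("augmentation: identity, involution, binarity and area scaling", {
  set.seed(5)
  img <- matrix(rnorm(64 * 64), 64, 64)
  msk <- matrix(0, 64, 64); msk[23:42, 20:39] <- 1

  ident <- augmentation_spec(0, c(1, 1), 0, 0)
  a <- augment_slice(img, msk, ident)
  expect_identical(a$image, img)

  hflip <- augmentation_spec(0, c(1, 1), 1, 0)
  once <- augment_slice(img, msk, hflip)
  twice <- augment_slice(once$image, once$mask, hflip)
  expect_equal(twice$image, img, tolerance = 1e-12)
  expect_equal(twice$mask, msk)

  zoom <- augmentation_spec(0, c(1.2, 1.2), 0, 0)
  z <- augment_slice(img, msk, zoom)
  expect_true(all(z$mask %in% c(0, 1)))
  expect_lt(abs(sum(z$mask) / sum(msk) - 1.2^2), 0.1 * 1.2^2)

  rot <- augmentation_spec(15, c(0.9, 1.1), 0.5, 0.5)
  r <- augment_slice(img, msk, rot)
  expect_true(all(r$mask %in% c(0, 1)))
  expect_equal(dim(r$image), dim(img))
})

test_that("a small learner trains, logs, and predicts deterministically", {
  cohort <- get_cohort("easy8", easy_phantom_config(n_exams = 10, seed = 20))
  l <- train_learner(cohort[1:8], cohort[9:10], config = unet_config(3, 4),
                     spec = preprocess_spec("zscore", bias_correct = FALSE),
                     epochs = 10, batch_size = 16, seed = 6, lr = 1e-2)
  tl <- l$training_log
  expect_equal(nrow(tl), 10)
  # learning happened: early losses exceed late losses
  expect_gt(mean(tl$train_loss[1:3]), mean(tl$train_loss[8:10]))
  expect_gt(tl$val_dice[10], 0.5)

  held <- cohort[[10]]
  pm1 <- predict_slices(l, held)
  pm2 <- predict_slices(l, held)
  expect_identical(pm1, pm2)
  expect_equal(dim(pm1), dim(held$image$voxels))
  expect_true(all(pm1 >= 0 & pm1 <= 1))

  expect_error(train_learner(list(), config = unet_config(2, 2)), "empty")
})

test_that("learner round-trips through its serialized directory", {
  cohort <- get_cohort("easy8", easy_phantom_config(n_exams = 10, seed = 20))
  l <- train_learner(cohort[1:4], cohort[5:6], config = unet_config(2, 2),
                     spec = preprocess_spec("minmax_volume", bias_correct = FALSE),
                     epochs = 1, batch_size = 16, seed = 7)
  td <- withr::local_tempdir()
  save_learner(l, file.path(td, "lrn"))
  back <- load_learner(file.path(td, "lrn"))
  expect_equal(back$params, l$params)
  expect_equal(back$preprocess$method, "minmax_volume")
  e <- cohort[[7]]
  expect_equal(predict_slices(back, e), predict_slices(l, e))
})

test_that("cross-validated training honors fold structure and counts", {
  cohort <- get_cohort("easy8", easy_phantom_config(n_exams = 10, seed = 20))
  v <- list(list(name = "zs", config = unet_config(2, 2),
                 preprocess = preprocess_spec("zscore", bias_correct = FALSE)))
  ls <- train_cv(cohort[1:6], k = 2, variants = v, epochs = 1, seed = 8)
  expect_length(ls, 2)
  expect_setequal(vapply(ls, function(l) l$fold_index, numeric(1)), 1:2)
  ids <- vapply(cohort[1:6], function(e) e$image$exam_id, character(1))
  for (l in ls) {
    val_ids <- setdiff(ids, l$train_ids)
    expect_length(val_ids, 3)
    expect_false(any(val_ids %in% l$train_ids))
  }
  # 6 variants x 5 folds instantiate exactly 30 learners
  ls30 <- train_cv(cohort, k = 5, variants = default_variants(),
                   seed = 9, dry_run = TRUE)
  expect_length(ls30, 30)
})
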