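# Base-learner training: dice loss, on-the-fly augmentation, single-learner
# training and K-fold cross-validated training of all variants.

DICE_EPS <- 1e-6

#' Dice-coefficient loss
#'
#' `1 - (2 * sum(p * y) + eps) / (sum(p) + sum(y) + eps)` over the whole
#' batch, with `eps = 1e-6` keeping the loss finite on empty masks. Value is
#' in \[0, 1\]; insensitive to the background class (only tumor overlap
#' counts), which suits the heavy tumor/background class imbalance.
#'
#' @param pred Probability array in \[0, 1\].
#' @param target Binary array of the same shape.
#' @param gradient If `TRUE`, also return `dpred`, the loss gradient.
#' @return The scalar loss, or (with `gradient`) a list `(loss, dpred)`.
#' @export
dice_loss <- function(pred, target, gradient = FALSE) {
  if (!identical(dim(pred), dim(target)) || length(pred) != length(target))
    stop("pred/target shape mismatch", call. = FALSE)
  num <- 2 * sum(pred * target) + DICE_EPS
  den <- sum(pred) + sum(target) + DICE_EPS
  loss <- 1 - num / den
  if (!gradient) return(loss)
  dpred <- -(2 * target * den - num) / den^2
  list(loss = loss, dpred = dpred)
}

#' Augmentation specification
#'
#' On-the-fly geometric augmentation: one random rotation, one random scale
#' (zoom about the slice center, cropped/padded back to the input size) and
#' independent horizontal/vertical flips, applied identically to image and
#' mask.
#'
#' @param rotation_max_deg Maximum absolute rotation, degrees.
#' @param scale_range Zoom factor range.
#' @param flip_h_prob,flip_v_prob Flip probabilities.
#' @return An object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(rotation_max_deg = 15, scale_range = c(0.9, 1.1),
                              flip_h_prob = 0.5, flip_v_prob = 0.5) {
  stopifnot(rotation_max_deg >= 0, length(scale_range) == 2, all(scale_range > 0),
            flip_h_prob >= 0, flip_h_prob <= 1, flip_v_prob >= 0, flip_v_prob <= 1)
  structure(list(rotation_max_deg = rotation_max_deg,
                 scale_range = as.numeric(scale_range),
                 flip_h_prob = flip_h_prob, flip_v_prob = flip_v_prob),
            class = "augmentation_spec")
}

#' Randomly augment an image/mask slice pair
#'
#' Draws the transform from the caller's RNG stream. The image is resampled
#' bilinearly, the mask by nearest neighbour (so it stays binary), both with
#' the identical geometric transform; regions mapped from outside the slice
#' are zero.
#'
#' @param image_slice,mask_slice Congruent 2D matrices.
#' @param spec An [augmentation_spec()].
#' @return List `(image, mask)` of transformed slices.
#' @export
augment_slice <- function(image_slice, mask_slice, spec = augmentation_spec()) {
  stopifnot(identical(dim(image_slice), dim(mask_slice)))
  theta <- runif(1, -spec$rotation_max_deg, spec$rotation_max_deg) * pi / 180
  scl <- runif(1, spec$scale_range[1], spec$scale_range[2])
  fh <- runif(1) < spec$flip_h_prob
  fv <- runif(1) < spec$flip_v_prob
  if (theta == 0 && scl == 1 && !fh && !fv)
    return(list(image = image_slice, mask = mask_slice))
  # inverse map: flip, rotate by -theta, unscale (bilinear image, nearest mask)
  warp_pair_cpp(image_slice, mask_slice, cos(-theta), sin(-theta), 1 / scl,
                as.integer(fv), as.integer(fh))
}

exam_slices <- function(x) {
  d <- dim(x$image$voxels)
  lapply(seq_len(d[1]), function(k)
    list(image = x$image$voxels[k, , ], mask = x$mask$voxels[k, , ],
         exam_id = x$image$exam_id, slice = k))
}

slices_to_batch <- function(slices, field) {
  h <- nrow(slices[[1]][[field]]); w <- ncol(slices[[1]][[field]])
  arr <- array(0, c(h, w, length(slices), 1L))
  for (i in seq_along(slices)) arr[, , i, 1] <- slices[[i]][[field]]
  arr
}

binary_dice <- function(pred_bin, ref_bin) {
  num <- 2 * sum(pred_bin * ref_bin)
  den <- sum(pred_bin) + sum(ref_bin)
  if (den == 0) return(1)
  num / den
}

predict_exam_probs <- function(net, x, batch_size = 16L) {
  sl <- exam_slices(x)
  d <- dim(x$image$voxels)
  out <- array(0, d)
  i <- 1L
  while (i <= length(sl)) {
    take <- sl[seq(i, min(i + batch_size - 1L, length(sl)))]
    xb <- slices_to_batch(take, "image")
    fw <- unet_forward(structure(net, class = "unet"), xb, training = FALSE)
    for (t in seq_along(take)) out[i + t - 1L, , ] <- fw$out[, , t, 1]
    i <- i + length(take)
  }
  out
}

#' Train a single base learner
#'
#' Applies the preprocessing variant to all exams, pools their slices,
#' shuffles them each epoch, augments on the fly, and optimizes the dice
#' loss with Adam. The mean training loss and the mean validation dice
#' (binarized at 0.5, per validation exam) are recorded per epoch. Fully
#' seeded; slices with empty masks are retained (the dice epsilon keeps the
#' loss finite).
#'
#' @param train,val Lists of [exam()] objects (train must be nonempty).
#' @param config A [unet_config()].
#' @param spec A [preprocess_spec()] (recorded on the learner so inference
#'   re-applies the identical preprocessing).
#' @param epochs Number of epochs (>= 1).
#' @param batch_size Slices per batch (default 16).
#' @param seed Integer seed for initialization, shuffling and augmentation.
#' @param lr Adam learning rate.
#' @param augmentation An [augmentation_spec()], or `NULL` to disable.
#' @param fold_index Cross-validation fold tag stored on the learner.
#' @param stop_val_dsc Optional early-stop: end training once the mean
#'   validation dice reaches this value (default `NULL`, run all epochs).
#' @return An object of class `trained_learner`.
#' @export
train_learner <- function(train, val = list(), config = unet_config(3, 4),
                          spec = preprocess_spec("zscore", bias_correct = FALSE),
                          epochs = 30L, batch_size = 16L, seed = 0L,
                          lr = 1e-3, augmentation = augmentation_spec(),
                          fold_index = NA_integer_, stop_val_dsc = NULL) {
  if (length(train) == 0) stop("empty training exam list", call. = FALSE)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  train_pp <- lapply(train, apply_preprocess, spec = spec)
  val_pp <- lapply(val, apply_preprocess, spec = spec)
  pool <- unlist(lapply(train_pp, exam_slices), recursive = FALSE)
  if (length(pool) == 0) stop("empty training slice pool", call. = FALSE)

  net <- build_unet(config, seed = derive_seed(seed, "init"))
  opt <- adam_init(net$params)
  log_rows <- vector("list", epochs)
  n_epochs_run <- 0L

  with_local_seed(derive_seed(seed, "epochs"), {
    for (ep in seq_len(epochs)) {
      perm <- sample(length(pool))
      losses <- c()
      i <- 1L
      while (i <= length(perm)) {
        idx <- perm[seq(i, min(i + batch_size - 1L, length(perm)))]
        batch <- pool[idx]
        if (!is.null(augmentation)) {
          batch <- lapply(batch, function(s) {
            a <- augment_slice(s$image, s$mask, augmentation)
            list(image = a$image, mask = a$mask)
          })
        }
        xb <- slices_to_batch(batch, "image")
        yb <- slices_to_batch(batch, "mask")
        fw <- unet_forward(net, xb, training = TRUE)
        net$state <- fw$state
        dl <- dice_loss(fw$out, yb, gradient = TRUE)
        losses <- c(losses, dl$loss)
        grads <- unet_backward(net, fw$cache, dl$dpred)
        st <- adam_step(net$params, grads, opt, lr = lr)
        net$params <- st$params
        opt <- st$state
        i <- i + length(idx)
      }
      val_dice <- NA_real_
      if (length(val_pp) > 0) {
        dices <- vapply(val_pp, function(v) {
          pr <- predict_exam_probs(net, v, batch_size)
          binary_dice(ifelse(pr >= 0.5, 1, 0), v$mask$voxels)
        }, numeric(1))
        val_dice <- mean(dices)
      }
      log_rows[[ep]] <- data.frame(epoch = ep, train_loss = mean(losses),
                                   val_dice = val_dice)
      n_epochs_run <- ep
      if (!is.null(stop_val_dsc) && is.finite(val_dice) && val_dice >= stop_val_dsc)
        break
    }
  })

  structure(list(params = net$params, state = net$state, config = config,
                 preprocess = spec, fold_index = fold_index,
                 training_log = do.call(rbind, log_rows[seq_len(n_epochs_run)]),
                 train_ids = vapply(train, function(e) e$image$exam_id, character(1)),
                 seed = as.integer(seed)),
            class = "trained_learner")
}

#' Predict per-voxel tumor probabilities for an exam
#'
#' Re-applies the learner's recorded preprocessing, then runs each slice
#' through the network in evaluation mode (batch-norm running statistics),
#' so inference is deterministic and independent of batch composition.
#'
#' @param learner A [train_learner()] result.
#' @param x An [exam()] whose grid satisfies the network's divisibility
#'   constraint.
#' @return 3D array (slices, rows, cols) of probabilities in \[0, 1\].
#' @export
predict_slices <- function(learner, x) {
  stopifnot(inherits(learner, "trained_learner"), inherits(x, "exam"))
  xp <- apply_preprocess(x, learner$preprocess)
  predict_exam_probs(list(config = learner$config, params = learner$params,
                          state = learner$state), xp)
}

#' Train all base learners by K-fold cross-validation
#'
#' For each preprocessing/architecture variant and each fold, trains one
#' learner on the out-of-fold exams with the fold as validation, yielding
#' `k * length(variants)` learners (the canonical 6 variants x 5 folds give
#' the 30 base learners of the ensemble). Nyul standard scales are trained
#' per fold on that fold's training exams only.
#'
#' @param train_exams List of [exam()] objects.
#' @param k Number of folds.
#' @param variants List of variants, each a list with elements `name`,
#'   `config` ([unet_config()]) and `preprocess` ([preprocess_spec()]).
#' @param epochs,batch_size,lr,augmentation,stop_val_dsc Passed to
#'   [train_learner()].
#' @param seed Master seed; each learner gets a derived seed.
#' @param dry_run If `TRUE`, instantiate every learner (initialized network,
#'   fold and variant tags) without running any optimization — useful to
#'   inspect or count the configuration cheaply.
#' @return List of `trained_learner` objects, variant-major then fold order,
#'   each tagged with `variant` and `fold_index`.
#' @export
train_cv <- function(train_exams, k = 5L, variants, epochs = 30L,
                     batch_size = 16L, seed = 0L, lr = 1e-3,
                     augmentation = augmentation_spec(), stop_val_dsc = NULL,
                     dry_run = FALSE) {
  if (length(variants) < 1) stop("need at least one variant", call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  ids <- vapply(train_exams, function(e) e$image$exam_id, character(1))
  folds <- make_folds(ids, k = k, seed = derive_seed(seed, "folds"))
  learners <- list()
  for (vi in seq_along(variants)) {
    v <- variants[[vi]]
    for (f in seq_len(k)) {
      fold_ids <- names(folds)[folds == f]
      tr <- train_exams[!ids %in% fold_ids]
      va <- train_exams[ids %in% fold_ids]
      spec <- v$preprocess
      if (dry_run) {
        net <- build_unet(v$config, seed = derive_seed(seed, "learner", vi, f))
        lr_ <- structure(list(params = net$params, state = net$state,
                              config = v$config, preprocess = spec,
                              fold_index = f, training_log = NULL,
                              train_ids = vapply(tr, function(e) e$image$exam_id,
                                                 character(1)),
                              seed = derive_seed(seed, "learner", vi, f)),
                         class = "trained_learner")
        lr_$variant <- v$name
        learners[[paste0(v$name, ".fold", f)]] <- lr_
        next
      }
      if (spec$method == "nyul" && is.null(spec$nyul_scale)) {
        vols <- lapply(tr, function(e) {
          if (spec$bias_correct) bias_correct(e$image) else e$image
        })
        spec$nyul_scale <- nyul_train(vols)
      }
      lr_ <- train_learner(tr, va, config = v$config, spec = spec,
                           epochs = epochs, batch_size = batch_size,
                           seed = derive_seed(seed, "learner", vi, f),
                           lr = lr, augmentation = augmentation,
                           fold_index = f, stop_val_dsc = stop_val_dsc)
      lr_$variant <- v$name
      learners[[paste0(v$name, ".fold", f)]] <- lr_
    }
  }
  learners
}

#' Save / load a trained learner
#'
#' One directory per learner: parameter state as an RDS file plus a JSON
#' sidecar with the configuration, preprocessing spec, fold, seed and
#' training log.
#'
#' @param learner A `trained_learner`.
#' @param dir Learner directory.
#' @return `dir` invisibly (saver); a `trained_learner` (loader).
#' @export
save_learner <- function(learner, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(params = learner$params, state = learner$state),
          file.path(dir, "weights.rds"))
  side <- list(config = unclass(learner$config),
               preprocess = list(method = learner$preprocess$method,
                                 bias_correct = learner$preprocess$bias_correct,
                                 nyul_scale = if (!is.null(learner$preprocess$nyul_scale))
                                   unclass(learner$preprocess$nyul_scale)),
               fold_index = learner$fold_index,
               variant = learner$variant %||% NA_character_,
               seed = learner$seed,
               train_ids = learner$train_ids,
               training_log = learner$training_log)
  jsonlite::write_json(side, file.path(dir, "learner.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", null = "null")
  invisible(dir)
}

#' @rdname save_learner
#' @export
load_learner <- function(dir) {
  w <- readRDS(file.path(dir, "weights.rds"))
  side <- jsonlite::read_json(file.path(dir, "learner.json"), simplifyVector = TRUE)
  cfg <- do.call(unet_config, side$config)
  ns_raw <- side$preprocess$nyul_scale
  ns <- if (!is.null(ns_raw) && length(ns_raw))
    nyul_scale(ns_raw$percentiles, ns_raw$standard_values)
  spec <- preprocess_spec(side$preprocess$method, side$preprocess$bias_correct, ns)
  structure(list(params = w$params, state = w$state, config = cfg,
                 preprocess = spec, fold_index = side$fold_index,
                 training_log = side$training_log,
                 train_ids = side$train_ids, seed = side$seed,
                 variant = side$variant),
            class = "trained_learner")
}
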