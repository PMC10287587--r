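# The Super Learner: cross-entropy SL loss over combined probability maps,
# simplex-constrained weight optimization, convex combination, thresholding.

SL_CLIP <- 1e-7

#' Ensemble weights on the probability simplex
#'
#' @param w Numeric vector with every element in \[0, 1\] and sum 1 (within
#'   1e-6); renormalized exactly on construction.
#' @return An object of class `ensemble_weights`.
#' @export
ensemble_weights <- function(w) {
  w <- as.numeric(w)
  if (length(w) < 1) stop("need at least one weight", call. = FALSE)
  if (any(w < -1e-9) || any(w > 1 + 1e-9))
    stop("weights must lie in [0, 1]", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-6)
    stop("weights must sum to 1 (within 1e-6)", call. = FALSE)
  structure(list(w = pmin(pmax(w, 0), 1) / sum(pmin(pmax(w, 0), 1))),
            class = "ensemble_weights")
}

#' Stack base-learner probability maps over a set of exams
#'
#' Runs every learner on every exam and flattens the per-voxel probabilities
#' into an `n_voxels x m` matrix aligned with the flattened ground-truth
#' masks, ready for [sl_loss()] / [fit_weights()].
#'
#' @param learners List of `trained_learner` objects (or precomputed
#'   probability maps, see `prob_maps`).
#' @param exams List of [exam()] objects.
#' @param prob_maps Optional precomputed maps: a list (one per learner) of
#'   lists (one 3D array per exam), bypassing inference.
#' @return An object of class `probability_stack`: list with `probs`
#'   (matrix), `learner_ids`, `exam_ids`, `exam_of_voxel`, `dims`.
#' @export
probability_stack <- function(learners, exams, prob_maps = NULL) {
  m <- length(learners)
  if (m < 1) stop("need at least one learner", call. = FALSE)
  exam_ids <- vapply(exams, function(e) e$image$exam_id, character(1))
  nvox_per <- vapply(exams, function(e) length(e$mask$voxels), numeric(1))
  probs <- matrix(0, sum(nvox_per), m)
  for (j in seq_len(m)) {
    maps <- if (is.null(prob_maps)) lapply(exams, function(e) predict_slices(learners[[j]], e))
    else prob_maps[[j]]
    probs[, j] <- unlist(lapply(maps, as.numeric), use.names = FALSE)
  }
  if (any(probs < -1e-9) || any(probs > 1 + 1e-9))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  lid <- names(learners)
  if (is.null(lid)) lid <- paste0("learner", seq_len(m))
  structure(list(probs = probs, learner_ids = lid, exam_ids = exam_ids,
                 exam_of_voxel = rep(exam_ids, times = nvox_per),
                 dims = lapply(exams, function(e) dim(e$mask$voxels))),
            class = "probability_stack")
}

#' Flatten ground-truth masks aligned with a probability stack
#'
#' @param exams List of [exam()] objects in stack order.
#' @return Numeric 0/1 vector.
#' @export
stack_truth <- function(exams) {
  unlist(lapply(exams, function(e) as.numeric(e$mask$voxels)), use.names = FALSE)
}

combined_probs <- function(stack, w) drop(stack$probs %*% w)

#' Super Learner loss
#'
#' The voxelwise cross-entropy of the convex combination of base-learner
#' probabilities against the ground truth,
#' `-sum_i [ y_i log(sum_j w_j p_ji) + (1 - y_i) log(1 - sum_j w_j p_ji) ]`,
#' summed over all voxels of all slices. The combined probability is clipped
#' to `[1e-7, 1 - 1e-7]` before the logarithms.
#'
#' @param weights An [ensemble_weights()] (or a bare simplex vector).
#' @param stack A [probability_stack()].
#' @param truth Flattened 0/1 ground truth aligned with the stack rows.
#' @return Finite scalar loss.
#' @export
sl_loss <- function(weights, stack, truth) {
  w <- if (inherits(weights, "ensemble_weights")) weights$w else ensemble_weights(weights)$w
  if (length(w) != ncol(stack$probs))
    stop("weight length does not match the number of learners", call. = FALSE)
  if (length(truth) != nrow(stack$probs))
    stop("truth length does not match the stack", call. = FALSE)
  p <- pmin(pmax(combined_probs(stack, w), SL_CLIP), 1 - SL_CLIP)
  -sum(truth * log(p) + (1 - truth) * log1p(-p))
}

#' Optimize the ensemble weights on the simplex
#'
#' Minimizes [sl_loss()] over the probability simplex. The weights are
#' parameterized as a softmax over unconstrained logits (initialized to zero,
#' so the starting point is the uniform weight `1/m`), which keeps every
#' iterate feasible, and optimized with full-batch Adam. When the loss stops
#' improving by more than `tol` for 10 consecutive epochs the step size is
#' halved; optimization ends after `epochs` epochs or once the step size has
#' been annealed below 1/64 of its starting value.
#'
#' @param stack A [probability_stack()] built on the tuning split.
#' @param truth Flattened 0/1 truth, see [stack_truth()].
#' @param epochs Epoch budget (default 200).
#' @param lr Adam learning rate on the logits.
#' @param tol Early-stop improvement tolerance.
#' @param seed Unused source of randomness kept for interface stability (the
#'   optimization is deterministic); retained so derived pipelines can thread
#'   seeds uniformly.
#' @return An object of class `sl_fit`: `weights` ([ensemble_weights()]),
#'   `loss_trajectory`, `epochs_run`.
#' @export
fit_weights <- function(stack, truth, epochs = 200L, lr = 0.2, tol = 1e-8,
                        seed = 0L) {
  m <- ncol(stack$probs)
  if (length(truth) != nrow(stack$probs))
    stop("truth length does not match the stack", call. = FALSE)
  if (all(truth == 0) || all(truth == 1)) {
    warning("degenerate truth (single class everywhere): keeping uniform weights",
            call. = FALSE)
    return(structure(list(weights = ensemble_weights(rep(1 / m, m)),
                          loss_trajectory = sl_loss(rep(1 / m, m), stack, truth),
                          epochs_run = 0L),
                     class = "sl_fit"))
  }
  theta <- numeric(m)
  opt <- adam_init(list(theta = theta))
  P <- stack$probs
  y <- truth
  softmax <- function(z) { e <- exp(z - max(z)); e / sum(e) }
  traj <- numeric(0)
  best <- Inf
  stall <- 0L
  epochs_run <- 0L
  lr_cur <- lr
  for (ep in seq_len(epochs)) {
    w <- softmax(theta)
    p <- drop(P %*% w)
    pc <- pmin(pmax(p, SL_CLIP), 1 - SL_CLIP)
    loss <- -sum(y * log(pc) + (1 - y) * log1p(-pc))
    inside <- (p > SL_CLIP) & (p < 1 - SL_CLIP)
    dLdp <- ifelse(inside, -y / pc + (1 - y) / (1 - pc), 0)
    dLdw <- drop(crossprod(P, dLdp))
    dtheta <- w * (dLdw - sum(w * dLdw))
    st <- adam_step(list(theta = theta), list(theta = dtheta), opt, lr = lr_cur)
    theta <- st$params$theta
    opt <- st$state
    traj <- c(traj, loss)
    epochs_run <- ep
    if (best - loss < tol) stall <- stall + 1L else stall <- 0L
    best <- min(best, loss)
    if (stall >= 10L) {
      # not improving at this step size: anneal, stop once fully settled
      lr_cur <- lr_cur / 2
      stall <- 0L
      if (lr_cur < lr / 64) break
    }
  }
  structure(list(weights = ensemble_weights(softmax(theta)),
                 loss_trajectory = traj, epochs_run = epochs_run),
            class = "sl_fit")
}

#' Combine a probability stack with ensemble weights
#'
#' The per-voxel convex combination `p_SL = sum_j w_j p_j`. For a stack built
#' over several exams the result is a list of per-exam 3D maps; a plain list
#' of per-learner 3D arrays for a single exam is also accepted.
#'
#' @param stack A [probability_stack()], or a list of m congruent 3D
#'   probability arrays for one exam.
#' @param weights An [ensemble_weights()].
#' @return A 3D probability map, or a named list of them (one per exam).
#' @export
combine_maps <- function(stack, weights) {
  w <- if (inherits(weights, "ensemble_weights")) weights$w else ensemble_weights(weights)$w
  if (inherits(stack, "probability_stack")) {
    if (length(w) != ncol(stack$probs)) stop("weight/learner count mismatch", call. = FALSE)
    p <- combined_probs(stack, w)
    out <- list()
    off <- 0L
    for (i in seq_along(stack$exam_ids)) {
      n <- prod(stack$dims[[i]])
      out[[stack$exam_ids[i]]] <- array(p[off + seq_len(n)], stack$dims[[i]])
      off <- off + n
    }
    if (length(out) == 1) out[[1]] else out
  } else {
    if (length(w) != length(stack)) stop("weight/learner count mismatch", call. = FALSE)
    out <- array(0, dim(stack[[1]]))
    for (j in seq_along(stack)) out <- out + w[j] * stack[[j]]
    out
  }
}

#' Threshold a probability map into a segmentation mask
#'
#' Voxel = 1 iff probability >= threshold (ties map to tumor, so a uniform
#' 0.5 map is all tumor rather than silently empty).
#'
#' @param pmap 3D probability array.
#' @param threshold Threshold in (0, 1); default 0.5.
#' @param spacing,exam_id Metadata for the resulting mask.
#' @return A [segmentation_mask()].
#' @export
binarize <- function(pmap, threshold = 0.5, spacing = c(1, 1, 1),
                     exam_id = "exam") {
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)", call. = FALSE)
  segmentation_mask(array(as.numeric(pmap >= threshold), dim(pmap)),
                    spacing = spacing, exam_id = exam_id)
}

#' Save / load ensemble weights as JSON
#'
#' @param fit An `sl_fit` (or [ensemble_weights()]) object.
#' @param path JSON path.
#' @param learner_ids Learner ids recorded alongside the weights.
#' @return `path` invisibly (writer); a list with `learner_ids`, `w`,
#'   `final_loss`, `epochs_run` (reader).
#' @export
write_weights <- function(fit, path, learner_ids = NULL) {
  w <- if (inherits(fit, "sl_fit")) fit$weights$w else fit$w
  jsonlite::write_json(
    list(learner_ids = learner_ids,
         w = w,
         final_loss = if (inherits(fit, "sl_fit")) utils::tail(fit$loss_trajectory, 1) else NA,
         epochs_run = if (inherits(fit, "sl_fit")) fit$epochs_run else NA),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
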