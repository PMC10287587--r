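# Overlap- and boundary-based evaluation of predicted masks, voxelwise ROC
# analysis, and per-location summary tables.

as_mask_array <- function(x) {
  if (inherits(x, "segmentation_mask")) x$voxels else x
}

check_congruent <- function(pred, ref) {
  if (!identical(dim(as_mask_array(pred)), dim(as_mask_array(ref))))
    stop("mask shape mismatch", call. = FALSE)
}

#' Voxelwise confusion counts
#'
#' @param pred,ref Congruent binary masks ([segmentation_mask()] or arrays).
#' @return Named numeric vector `(TP, FP, TN, FN)`; the four counts sum to
#'   the total voxel count.
#' @export
confusion_counts <- function(pred, ref) {
  check_congruent(pred, ref)
  p <- as_mask_array(pred); r <- as_mask_array(ref)
  tp <- sum(p == 1 & r == 1)
  fp <- sum(p == 1 & r == 0)
  fn <- sum(p == 0 & r == 1)
  tn <- sum(p == 0 & r == 0)
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

#' Overlap metrics: DSC, sensitivity, specificity
#'
#' `DSC = 2TP / (2TP + FP + FN)`, `sensitivity = TP / (TP + FN)`,
#' `specificity = TN / (TN + FP)`. Two empty masks give DSC 1 with a warning
#' (nothing to find, nothing found); an empty reference makes sensitivity
#' `NaN`-free via the same convention used in the reports (flagged `NA`).
#'
#' @param pred,ref Congruent binary masks.
#' @return Scalar in \[0, 1\] (or `NA` where undefined).
#' @export
dsc <- function(pred, ref) {
  cc <- confusion_counts(pred, ref)
  den <- 2 * cc["TP"] + cc["FP"] + cc["FN"]
  if (den == 0) {
    warning("both masks empty: DSC defined as 1", call. = FALSE)
    return(1)
  }
  unname(2 * cc["TP"] / den)
}

#' @rdname dsc
#' @export
sensitivity <- function(pred, ref) {
  cc <- confusion_counts(pred, ref)
  if (cc["TP"] + cc["FN"] == 0) return(NA_real_)
  unname(cc["TP"] / (cc["TP"] + cc["FN"]))
}

#' @rdname dsc
#' @export
specificity <- function(pred, ref) {
  cc <- confusion_counts(pred, ref)
  if (cc["TN"] + cc["FP"] == 0) return(NA_real_)
  unname(cc["TN"] / (cc["TN"] + cc["FP"]))
}

# Boundary voxels: mask voxels with at least one face-adjacent background
# neighbour (outside the grid counts as background). Returns an n x 3 matrix
# of (slice, row, col) indices.
boundary_voxels <- function(mask) {
  m <- as_mask_array(mask) == 1
  d <- dim(m)
  interior <- array(TRUE, d)
  shift_and <- function(acc, axis, off) {
    nb <- array(FALSE, d)
    n <- d[axis]
    src <- seq_len(n) + off
    ok <- src >= 1 & src <= n
    if (axis == 1) nb[which(ok), , ] <- m[src[ok], , ]
    if (axis == 2) nb[, which(ok), ] <- m[, src[ok], ]
    if (axis == 3) nb[, , which(ok)] <- m[, , src[ok]]
    acc & nb
  }
  for (axis in 1:3) {
    if (d[axis] == 1) { interior[] <- FALSE; break }
    interior <- shift_and(interior, axis, -1L)
    interior <- shift_and(interior, axis, 1L)
  }
  idx <- which(m & !(m & interior))
  arrayInd(idx, d)
}

directed_min_dists <- function(a_mm, b_mm) {
  # squared-distance matrix via |a|^2 + |b|^2 - 2 a.b, chunked over rows
  nb2 <- rowSums(b_mm^2)
  chunk <- max(1L, floor(5e6 / nrow(b_mm)))
  out <- numeric(nrow(a_mm))
  i <- 1L
  while (i <= nrow(a_mm)) {
    rows <- seq(i, min(i + chunk - 1L, nrow(a_mm)))
    aa <- a_mm[rows, , drop = FALSE]
    d2 <- outer(rowSums(aa^2), nb2, "+") - 2 * tcrossprod(aa, b_mm)
    out[rows] <- sqrt(pmax(apply(d2, 1, min), 0))
    i <- i + length(rows)
  }
  out
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' Nearest-neighbour Euclidean distances between the boundary voxels of the
#' two masks, computed in mm with anisotropic spacing honored, in both
#' directions; HD95 is the 95th percentile (linear interpolation) of the
#' pooled directed distances — symmetric in its arguments by construction.
#' If either mask is empty the result is `NA` (undefined), not an error.
#'
#' @param pred,ref Congruent [segmentation_mask()] objects (arrays accepted,
#'   with `spacing` taken from the masks or the `spacing` argument).
#' @param spacing Voxel spacing `(dz, dy, dx)` in mm, used when bare arrays
#'   are passed.
#' @param slicewise If `TRUE`, distances are computed within each 2D slice
#'   (in-plane mm only) and pooled across slices where both masks have
#'   boundary voxels; default is fully 3D.
#' @return HD95 in mm, or `NA_real_` if undefined.
#' @export
hd95 <- function(pred, ref, spacing = NULL, slicewise = FALSE) {
  check_congruent(pred, ref)
  if (is.null(spacing))
    spacing <- if (inherits(pred, "segmentation_mask")) pred$spacing
  else if (inherits(ref, "segmentation_mask")) ref$spacing
  else c(1, 1, 1)
  p <- as_mask_array(pred); r <- as_mask_array(ref)
  if (sum(p) == 0 || sum(r) == 0) return(NA_real_)
  if (slicewise) {
    pooled <- c()
    for (k in seq_len(dim(p)[1])) {
      pk <- array(p[k, , ], c(1, dim(p)[2:3]))
      rk <- array(r[k, , ], c(1, dim(p)[2:3]))
      if (sum(pk) == 0 || sum(rk) == 0) next
      bp <- boundary_voxels(pk); br <- boundary_voxels(rk)
      bp_mm <- sweep(bp[, 2:3, drop = FALSE], 2, spacing[2:3], "*")
      br_mm <- sweep(br[, 2:3, drop = FALSE], 2, spacing[2:3], "*")
      pooled <- c(pooled, directed_min_dists(bp_mm, br_mm),
                  directed_min_dists(br_mm, bp_mm))
    }
    if (length(pooled) == 0) return(NA_real_)
    return(unname(quantile(pooled, 0.95, type = 7)))
  }
  bp <- boundary_voxels(p); br <- boundary_voxels(r)
  bp_mm <- sweep(bp, 2, spacing, "*")
  br_mm <- sweep(br, 2, spacing, "*")
  pooled <- c(directed_min_dists(bp_mm, br_mm), directed_min_dists(br_mm, bp_mm))
  unname(quantile(pooled, 0.95, type = 7))
}

#' Voxelwise ROC curve and AUC
#'
#' ROC over all voxels of an exam with thresholds at the unique predicted
#' probabilities. The AUC is computed from the rank-sum statistic with ties
#' handled by rank averaging (identical to the trapezoid rule on the tie-aware
#' curve), so a constant map gives AUC 0.5.
#'
#' @param pmap 3D probability array.
#' @param ref Congruent binary reference mask containing both classes.
#' @return List with `curve` (data.frame: threshold, fpr, tpr) and `auc`;
#'   `auc` is `NA` when the reference holds a single class.
#' @export
roc_auc <- function(pmap, ref) {
  r <- as_mask_array(ref)
  if (!identical(dim(as_mask_array(pmap)), dim(r)))
    stop("shape mismatch", call. = FALSE)
  p <- as.numeric(as_mask_array(pmap))
  y <- as.numeric(r)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    warning("single-class reference: ROC undefined", call. = FALSE)
    return(list(curve = NULL, auc = NA_real_))
  }
  rk <- rank(p)
  auc <- (sum(rk[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(p, decreasing = TRUE)
  ps <- p[ord]; ys <- y[ord]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  last <- !duplicated(ps, fromLast = TRUE)  # last index of each threshold block
  curve <- data.frame(threshold = ps[last],
                      fpr = fp[last] / n0, tpr = tp[last] / n1)
  curve <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), curve)
  list(curve = curve, auc = auc)
}

#' Per-exam metrics report
#'
#' Convenience wrapper producing one report row for a predicted mask (and
#' optionally its probability map for AUC) against the reference.
#'
#' @param pred Predicted [segmentation_mask()].
#' @param ref Reference [segmentation_mask()].
#' @param pmap Optional probability map for the AUC column.
#' @param exam_id,model Identifiers recorded in the row.
#' @return One-row data.frame: exam_id, model, dsc, sensitivity,
#'   specificity, hd95_mm, auc.
#' @export
evaluate_exam <- function(pred, ref, pmap = NULL, exam_id = "exam",
                          model = "model") {
  auc <- NA_real_
  if (!is.null(pmap)) {
    ra <- suppressWarnings(roc_auc(pmap, ref))
    auc <- ra$auc
  }
  data.frame(exam_id = exam_id, model = model,
             dsc = suppressWarnings(dsc(pred, ref)),
             sensitivity = sensitivity(pred, ref),
             specificity = specificity(pred, ref),
             hd95_mm = hd95(pred, ref),
             auc = auc,
             stringsAsFactors = FALSE)
}

#' Per-location summary table
#'
#' Means of each metric per tumor location and overall, for the individual
#' base learners and the Super Learner, plus improvement rows: the signed
#' difference `SL - individual` for the overlap metrics (whose range is
#' \[0, 1\]) and the percent reduction `(individual - SL) / individual * 100`
#' for HD95 (whose scale is arbitrary). Undefined HD95 entries are excluded
#' from the means, with the number of contributing exams reported.
#'
#' @param reports Data.frame of [evaluate_exam()] rows; the `model` column
#'   distinguishes base learners from the Super Learner.
#' @param labels Named character vector mapping exam id to location label.
#' @param sl_model Value of `model` identifying the Super Learner rows.
#' @param exclude_models Models ignored entirely (e.g. an equal-weights
#'   reference run).
#' @return Data.frame with columns metric, group, one column per location,
#'   and ALL.
#' @export
summarize_by_location <- function(reports, labels, sl_model = "super_learner",
                                  exclude_models = character(0)) {
  stopifnot(is.data.frame(reports), all(c("exam_id", "model") %in% names(reports)))
  if (!all(reports$exam_id %in% names(labels)))
    stop("unlabeled exam id in reports", call. = FALSE)
  loc <- unname(labels[reports$exam_id])
  if (any(is.na(loc))) stop("unknown location label", call. = FALSE)
  reports$location <- loc
  reports <- reports[!reports$model %in% exclude_models, , drop = FALSE]
  is_sl <- reports$model == sl_model
  locations <- unique(reports$location)
  metrics <- c("dsc", "sensitivity", "specificity", "hd95_mm")
  cell_mean <- function(rows, metric) {
    v <- reports[[metric]][rows]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  out <- list()
  for (metric in metrics) {
    ind <- vapply(locations, function(L)
      cell_mean(!is_sl & reports$location == L, metric), numeric(1))
    sl <- vapply(locations, function(L)
      cell_mean(is_sl & reports$location == L, metric), numeric(1))
    ind_all <- cell_mean(!is_sl, metric)
    sl_all <- cell_mean(is_sl, metric)
    imp <- if (metric == "hd95_mm") (ind - sl) / ind * 100 else sl - ind
    imp_all <- if (metric == "hd95_mm") (ind_all - sl_all) / ind_all * 100
    else sl_all - ind_all
    rows <- rbind(
      data.frame(metric = metric, group = "individual",
                 t(setNames(ind, locations)), ALL = ind_all,
                 check.names = FALSE),
      data.frame(metric = metric, group = "super_learner",
                 t(setNames(sl, locations)), ALL = sl_all,
                 check.names = FALSE),
      data.frame(metric = metric,
                 group = if (metric == "hd95_mm") "improvement_pct" else "improvement",
                 t(setNames(imp, locations)), ALL = imp_all,
                 check.names = FALSE))
    out[[metric]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  n_def <- sum(!is.na(reports$hd95_mm[is_sl]))
  attr(res, "hd95_n_defined") <- n_def
  res
}
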