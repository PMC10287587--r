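# Bias-field correction and the four intensity normalization/standardization
# methods that define the preprocessing variants feeding the base learners.

#' Nyul standard scale
#'
#' Trained landmark percentiles and their intensities on the standard scale.
#'
#' @param percentiles Strictly increasing values in (0, 100); the first and
#'   last act as the low/high anchors.
#' @param standard_values Strictly increasing intensities, same length.
#' @return An object of class `nyul_scale`.
#' @export
nyul_scale <- function(percentiles, standard_values) {
  percentiles <- as.numeric(percentiles)
  standard_values <- as.numeric(standard_values)
  if (length(percentiles) < 3 || length(percentiles) != length(standard_values))
    stop("need >= 3 percentiles with matching standard values", call. = FALSE)
  if (any(diff(percentiles) <= 0) || any(percentiles <= 0) || any(percentiles >= 100))
    stop("percentiles must be strictly increasing within (0, 100)", call. = FALSE)
  if (any(diff(standard_values) <= 0))
    stop("standard values must be strictly increasing", call. = FALSE)
  structure(list(percentiles = percentiles, standard_values = standard_values),
            class = "nyul_scale")
}

#' Save / load a Nyul scale as JSON
#' @param scale A [nyul_scale()].
#' @param path JSON file path.
#' @return `path` invisibly (writer); a [nyul_scale()] (reader).
#' @export
write_nyul_scale <- function(scale, path) {
  jsonlite::write_json(unclass(scale), path, digits = NA)
  invisible(path)
}

#' @rdname write_nyul_scale
#' @export
read_nyul_scale <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nyul_scale(x$percentiles, x$standard_values)
}

#' Preprocessing specification
#'
#' One of the preprocessing variants: optional bias-field correction followed
#' by a normalization method.
#'
#' @param method `"zscore"`, `"minmax_volume"`, `"minmax_slice"` or `"nyul"`.
#' @param bias_correct Apply [bias_correct()] before normalizing?
#' @param nyul_scale A [nyul_scale()]; required iff `method = "nyul"`.
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(method = c("zscore", "minmax_volume", "minmax_slice", "nyul"),
                            bias_correct = TRUE, nyul_scale = NULL) {
  method <- match.arg(method)
  if (method == "nyul" && !is.null(nyul_scale) && !inherits(nyul_scale, "nyul_scale"))
    stop("nyul_scale must be a nyul_scale object", call. = FALSE)
  if (method != "nyul" && !is.null(nyul_scale))
    stop("nyul_scale only applies to method = 'nyul'", call. = FALSE)
  structure(list(method = method, bias_correct = isTRUE(bias_correct),
                 nyul_scale = nyul_scale),
            class = "preprocess_spec")
}

# ---- Bias-field correction --------------------------------------------

# Tensor-product cubic B-spline design matrix over voxel coordinates.
bias_basis <- function(shape, spacing, spline_scale) {
  ax_basis <- function(n, sp) {
    coords <- (seq_len(n) - 0.5) * sp
    extent <- n * sp
    ndf <- max(4L, min(8L, as.integer(round(extent / spline_scale)) + 3L))
    splines::bs(coords, df = ndf, intercept = TRUE)
  }
  Bz <- ax_basis(shape[1], spacing[1])
  By <- ax_basis(shape[2], spacing[2])
  Bx <- ax_basis(shape[3], spacing[3])
  list(Bz = Bz, By = By, Bx = Bx)
}

# Evaluate the tensor-product field from a coefficient array.
eval_field <- function(basis, coef) {
  nz <- nrow(basis$Bz); ny <- nrow(basis$By); nx <- nrow(basis$Bx)
  kz <- ncol(basis$Bz); ky <- ncol(basis$By); kx <- ncol(basis$Bx)
  dim(coef) <- c(kz, ky * kx)
  t1 <- basis$Bz %*% coef                       # nz x (ky kx)
  t1 <- array(t1, c(nz, ky, kx))
  out <- array(0, c(nz, ny, nx))
  Ty <- basis$By; Tx <- basis$Bx
  for (k in seq_len(nz)) {
    out[k, , ] <- Ty %*% t1[k, , ] %*% t(Tx)
  }
  out
}

bias_cache <- new.env(parent = emptyenv())

#' Correct multiplicative bias-field inhomogeneity
#'
#' Estimates a spatially smooth, strictly positive multiplicative field from
#' the volume and divides it out. The field is fitted in the log domain as a
#' tensor-product cubic B-spline surface by iteratively reweighted least
#' squares with Tukey bisquare weights, so smooth coil/field inhomogeneity is
#' captured while tissue structure (tumor, fat) is progressively downweighted
#' as outliers. The fitted field is normalized to geometric mean 1 before
#' division; output is non-negative, finite, and deterministic.
#'
#' Results are memoised in a package-local cache keyed by exam id, voxel
#' checksums and parameters, since ensemble inference applies the identical
#' correction once per base learner; disable with
#' `options(slseg.bias_cache = FALSE)`.
#'
#' @param volume An [image_volume()] with non-negative intensities (an
#'   all-zero volume is an error).
#' @param max_iterations IRLS iteration cap (default 50; stops earlier when
#'   the field change drops below 1e-4).
#' @param spline_scale Control-point spacing of the B-spline field in mm;
#'   default one quarter of the in-plane field of view.
#' @return The corrected [image_volume()].
#' @export
bias_correct <- function(volume, max_iterations = 50L, spline_scale = NULL) {
  stopifnot(inherits(volume, "image_volume"))
  v <- volume$voxels
  stop_if_not_finite(v, "volume")
  if (min(v) < 0) v <- v - min(v)
  if (max(v) <= 0) stop("all-zero volume has no bias field to estimate", call. = FALSE)
  shape <- dim(v)
  sp <- volume$spacing
  if (is.null(spline_scale))
    spline_scale <- 0.25 * max(shape[2] * sp[2], shape[3] * sp[3])

  use_cache <- !isFALSE(getOption("slseg.bias_cache", TRUE))
  key <- NULL
  if (use_cache) {
    key <- paste(volume$exam_id, paste(shape, collapse = "x"),
                 format(sum(v), digits = 17), format(sum(v * v), digits = 17),
                 max_iterations, format(spline_scale, digits = 10), sep = "|")
    hit <- bias_cache[[key]]
    if (!is.null(hit)) return(image_volume(hit, sp, volume$exam_id))
  }

  eps <- 1e-3 * mean(v[v > 0])
  fg <- v > eps
  logv <- log(pmax(v, eps))
  basis <- bias_basis(shape, sp, spline_scale)
  # design matrix on a regular subsample of foreground voxels; the field is
  # evaluated on the full grid afterwards
  idx_fg <- which(fg)
  step <- max(1L, floor(length(idx_fg) / 4000))
  idx <- idx_fg[seq(1, length(idx_fg), by = step)]
  ar <- arrayInd(idx, shape)
  X <- t(vapply(seq_along(idx), function(t) {
    kronecker(basis$Bx[ar[t, 3], ], kronecker(basis$By[ar[t, 2], ], basis$Bz[ar[t, 1], ]))
  }, numeric(ncol(basis$Bz) * ncol(basis$By) * ncol(basis$Bx))))
  yv <- logv[idx]
  XtX <- crossprod(X)
  ridge <- diag(1e-6 * mean(diag(XtX)), ncol(X))

  # iterate: sharpen the current corrected log intensities to a
  # piecewise-constant tissue estimate (k-means with deterministic quantile
  # initialization), then spline-fit the residual log field
  sharpen <- function(r, k = 4L) {
    ctr <- unique(quantile(r, seq(0.5, k - 0.5) / k, names = FALSE))
    if (length(ctr) < 2 || sd(r) < 1e-8) return(rep(mean(r), length(r)))
    km <- suppressWarnings(stats::kmeans(r, centers = matrix(ctr), iter.max = 25))
    km$centers[km$cluster]
  }
  # Each iteration: sharpen the current corrected log intensities, then one
  # Tukey-bisquare-weighted spline fit of the residual log field. The robust
  # weights (carried across iterations) suppress voxels whose residual is
  # dominated by class misassignment rather than smooth bias.
  logb_pts <- numeric(length(yv))
  coef <- numeric(ncol(X))
  w <- rep(1, length(yv))
  for (it in seq_len(max_iterations)) {
    u_hat <- sharpen(yv - logb_pts)
    d <- yv - u_hat
    Xw <- X * w
    fit <- drop(solve(crossprod(Xw, X) + ridge, crossprod(Xw, d)))
    res <- d - drop(X %*% fit)
    s <- stats::median(abs(res - stats::median(res))) * 1.4826
    if (s > 1e-10) {
      u <- res / (4.685 * s)
      w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    }
    new_pts <- drop(X %*% fit)
    new_pts <- new_pts - mean(new_pts)
    done <- it > 2 && max(abs(new_pts - logb_pts)) < 1e-4
    logb_pts <- new_pts
    coef <- fit
    if (done) break
  }
  log_field <- eval_field(basis, coef)
  log_field <- log_field - mean(log_field[fg])
  # guard against extrapolation outside the fitted support
  lim <- range(logb_pts)
  log_field <- pmin(pmax(log_field, lim[1] - 0.1), lim[2] + 0.1)
  field <- exp(log_field)
  out <- v / field
  if (use_cache) {
    if (length(ls(bias_cache)) > 500) rm(list = ls(bias_cache), envir = bias_cache)
    bias_cache[[key]] <- out
  }
  image_volume(out, sp, volume$exam_id)
}

# ---- Normalization -----------------------------------------------------

#' Z-score normalization over the whole 3D volume
#'
#' `(x - mean) / sd` with the population sd. A constant volume (sd below
#' 1e-12) yields all zeros with a warning, so batch pipelines survive blank
#' padded slices.
#'
#' @param volume An [image_volume()] with at least 2 voxels.
#' @return The normalized [image_volume()].
#' @export
normalize_zscore <- function(volume) {
  stopifnot(inherits(volume, "image_volume"))
  v <- volume$voxels
  if (length(v) < 2) stop("need at least 2 voxels", call. = FALSE)
  stop_if_not_finite(v, "volume")
  mu <- mean(v)
  sdev <- sqrt(mean((v - mu)^2))
  out <- if (sdev < 1e-12) {
    warning("constant volume: z-score undefined, returning zeros", call. = FALSE)
    array(0, dim(v))
  } else (v - mu) / sdev
  image_volume(out, volume$spacing, volume$exam_id)
}

minmax01 <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi - lo < 1e-12) return(NULL)
  (x - lo) / (hi - lo)
}

#' Min-max normalization over the whole 3D volume
#'
#' `(x - min) / (max - min)`, giving range \[0, 1\]. A constant volume yields
#' zeros with a warning.
#'
#' @inheritParams normalize_zscore
#' @return The normalized [image_volume()].
#' @export
normalize_minmax_volume <- function(volume) {
  stopifnot(inherits(volume, "image_volume"))
  v <- volume$voxels
  stop_if_not_finite(v, "volume")
  out <- minmax01(v)
  if (is.null(out)) {
    warning("constant volume: min-max undefined, returning zeros", call. = FALSE)
    out <- array(0, dim(v))
  }
  image_volume(array(out, dim(v)), volume$spacing, volume$exam_id)
}

#' Min-max normalization applied independently per slice
#'
#' @inheritParams normalize_zscore
#' @return The normalized [image_volume()]; constant slices become zeros.
#' @export
normalize_minmax_slice <- function(volume) {
  stopifnot(inherits(volume, "image_volume"))
  v <- volume$voxels
  stop_if_not_finite(v, "volume")
  out <- array(0, dim(v))
  for (k in seq_len(dim(v)[1])) {
    s <- minmax01(v[k, , ])
    if (!is.null(s)) out[k, , ] <- s
  }
  image_volume(out, volume$spacing, volume$exam_id)
}

nyul_landmarks <- function(v, percentiles) {
  nz <- v[v != 0]
  thr <- if (length(nz)) mean(nz) else 0
  fgv <- v[v > thr]
  if (length(fgv) < length(percentiles))
    stop("too few foreground voxels for landmark estimation", call. = FALSE)
  quantile(fgv, percentiles / 100, names = FALSE, type = 7)
}

#' Train a Nyul histogram-standardization scale
#'
#' Phase one of Nyul standardization. For each training volume, landmark
#' intensities at the given percentiles are computed over foreground voxels
#' (those above the mean of the volume's nonzero intensities) and mapped
#' linearly so the low/high anchor landmarks hit `standard_range`; the
#' standard scale is the per-landmark mean of these mapped values across
#' volumes.
#'
#' @param volumes List of [image_volume()] objects (>= 1).
#' @param percentiles Strictly increasing landmark percentiles in (0, 100);
#'   default `c(1, 10, 20, ..., 90, 99)`.
#' @param standard_range Intensities `(s_min, s_max)` the anchors map to.
#' @return A [nyul_scale()].
#' @export
nyul_train <- function(volumes, percentiles = c(1, seq(10, 90, by = 10), 99),
                       standard_range = c(0, 100)) {
  if (length(volumes) == 0) stop("need at least one training volume", call. = FALSE)
  percentiles <- as.numeric(percentiles)
  if (any(diff(percentiles) <= 0) || any(percentiles <= 0) || any(percentiles >= 100))
    stop("percentiles must be strictly increasing within (0, 100)", call. = FALSE)
  s_min <- standard_range[1]; s_max <- standard_range[2]
  mapped <- vapply(volumes, function(vol) {
    lm_ <- nyul_landmarks(vol$voxels, percentiles)
    p1 <- lm_[1]; pk <- lm_[length(lm_)]
    if (pk - p1 <= 0) stop("degenerate landmarks in training volume ",
                           vol$exam_id, call. = FALSE)
    s_min + (lm_ - p1) / (pk - p1) * (s_max - s_min)
  }, numeric(length(percentiles)))
  sv <- rowMeans(mapped)
  if (any(diff(sv) <= 0))
    stop("learned standard values are not strictly increasing (degenerate cohort)",
         call. = FALSE)
  nyul_scale(percentiles, sv)
}

#' Apply a trained Nyul scale to a volume
#'
#' Phase two: the volume's own landmark intensities are mapped onto the
#' standard values by piecewise-linear interpolation, extrapolating linearly
#' beyond the anchor landmarks. The map is monotone non-decreasing in input
#' intensity.
#'
#' @param volume An [image_volume()].
#' @param scale A [nyul_scale()].
#' @return The standardized [image_volume()].
#' @export
nyul_apply <- function(volume, scale) {
  stopifnot(inherits(volume, "image_volume"), inherits(scale, "nyul_scale"))
  v <- volume$voxels
  lm_ <- nyul_landmarks(v, scale$percentiles)
  if (any(diff(lm_) <= 0))
    stop("volume has degenerate (non-increasing) landmarks", call. = FALSE)
  sv <- scale$standard_values
  k <- length(lm_)
  out <- approx(lm_, sv, xout = as.vector(v), rule = 2)$y
  # linear extrapolation beyond the anchors with the end-segment slopes
  lo <- as.vector(v) < lm_[1]
  hi <- as.vector(v) > lm_[k]
  if (any(lo)) out[lo] <- sv[1] + (as.vector(v)[lo] - lm_[1]) *
      (sv[2] - sv[1]) / (lm_[2] - lm_[1])
  if (any(hi)) out[hi] <- sv[k] + (as.vector(v)[hi] - lm_[k]) *
      (sv[k] - sv[k - 1]) / (lm_[k] - lm_[k - 1])
  image_volume(array(out, dim(v)), volume$spacing, volume$exam_id)
}

#' @importFrom stats approx lm.wfit median
NULL

#' Apply a preprocessing variant to an exam
#'
#' Composes [bias_correct()] (if enabled) with the named normalization. The
#' mask is never touched.
#'
#' @param x An [exam()].
#' @param spec A [preprocess_spec()]; for `method = "nyul"` the spec must
#'   carry a trained [nyul_scale()].
#' @return The preprocessed [exam()].
#' @export
apply_preprocess <- function(x, spec) {
  stopifnot(inherits(x, "exam"), inherits(spec, "preprocess_spec"))
  vol <- x$image
  if (spec$bias_correct) vol <- bias_correct(vol)
  vol <- switch(spec$method,
    zscore = normalize_zscore(vol),
    minmax_volume = normalize_minmax_volume(vol),
    minmax_slice = normalize_minmax_slice(vol),
    nyul = {
      if (is.null(spec$nyul_scale))
        stop("method 'nyul' requires a trained nyul_scale in the spec", call. = FALSE)
      nyul_apply(vol, spec$nyul_scale)
    })
  exam(vol, x$mask, location_label = x$location_label, site_tag = x$site_tag)
}
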