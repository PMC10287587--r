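# Seeded synthetic MR-like phantom cohort emulating multicenter heterogeneity:
# smooth multiplicative bias fields, site-dependent intensity conventions,
# variable tumor size/contrast/position, additive noise.

#' Phantom cohort configuration
#'
#' Defines the statistical structure of the synthetic cohort: a dark
#' background, mid-intensity soft tissue, a bright subcutaneous fat band, and
#' an ellipsoidal (optionally lobulated) fat-like tumor whose mean intensity
#' is the fat signal times a contrast factor. Each exam is multiplied by a
#' smooth bias field, passed through its site's intensity style
#' (offset/scale/gamma), and corrupted with Gaussian noise.
#'
#' Defaults are desk-scale: 60 exams of 8 x 64 x 64 voxels, tumor in-plane
#' radii 6-14 voxels, tumor/fat contrast 1.1-1.6, bias amplitude 0.3 with
#' correlation length 16 voxels, noise sd 0.05, three site styles.
#'
#' @param n_exams Number of exams.
#' @param shape Grid shape `(slices, rows, cols)`.
#' @param tumor_radius_range In-plane ellipsoid radii range, voxels.
#' @param tumor_contrast_range Tumor mean intensity relative to the fat band
#'   signal (1 = isointense with fat, the hard case).
#' @param bias_amplitude Peak-to-mean ratio of the multiplicative bias field
#'   (0 disables it).
#' @param bias_smoothness Bias correlation length, voxels.
#' @param noise_sd Additive Gaussian noise sd, intensity units (applied after
#'   the site style).
#' @param site_styles List of numeric triples `(intensity_offset,
#'   intensity_scale, gamma)`, cycled round-robin over exams.
#' @param location_labels Labels assigned round-robin, see [exam()].
#' @param lobulation If `TRUE`, tumors are unions of 1-3 overlapping
#'   ellipsoids, mimicking insinuating lipomatous shapes.
#' @param spacing Voxel spacing `(dz, dy, dx)` in mm.
#' @param seed Integer master seed; `(seed, index)` fully determines an exam.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(n_exams = 60L,
                           shape = c(8L, 64L, 64L),
                           tumor_radius_range = c(6, 14),
                           tumor_contrast_range = c(1.1, 1.6),
                           bias_amplitude = 0.3,
                           bias_smoothness = 16,
                           noise_sd = 0.05,
                           site_styles = list(c(0, 1, 1),
                                              c(12, 1.8, 0.9),
                                              c(3, 0.6, 1.1)),
                           location_labels = c("DUL", "DLL", "PUL", "PLL", "T"),
                           lobulation = TRUE,
                           spacing = c(4, 1, 1),
                           seed = 0L) {
  stopifnot(n_exams >= 1, length(shape) == 3, all(shape >= 1),
            diff(tumor_radius_range) >= 0, diff(tumor_contrast_range) >= 0,
            bias_amplitude >= 0, bias_smoothness > 0, noise_sd >= 0,
            length(site_styles) >= 1)
  structure(list(n_exams = as.integer(n_exams), shape = as.integer(shape),
                 tumor_radius_range = tumor_radius_range,
                 tumor_contrast_range = tumor_contrast_range,
                 bias_amplitude = bias_amplitude,
                 bias_smoothness = bias_smoothness,
                 noise_sd = noise_sd, site_styles = site_styles,
                 location_labels = location_labels,
                 lobulation = isTRUE(lobulation),
                 spacing = spacing, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Simulate a smooth multiplicative bias field
#'
#' Low-pass filtered seeded Gaussian noise, exponentiated and normalized to
#' mean 1. `amplitude` sets the peak-to-mean ratio (0 returns all ones);
#' `smoothness` is the Gaussian correlation length in voxels.
#'
#' @param shape Grid shape `(slices, rows, cols)`.
#' @param amplitude Peak-to-mean ratio, >= 0.
#' @param smoothness Correlation length in voxels.
#' @param seed Integer seed.
#' @return A strictly positive 3D array with mean 1 (within 1e-2).
#' @export
make_bias_field <- function(shape, amplitude = 0.3, smoothness = 16, seed = 0L) {
  shape <- as.integer(shape)
  if (any(shape <= 0)) stop("shape must be positive", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (amplitude == 0) return(array(1, shape))
  n <- with_local_seed(seed, array(rnorm(prod(shape)), shape))
  # isotropic correlation length in voxels; thin stacks end up nearly
  # constant along the slice axis, as a coil bias sampled at coarse slice
  # spacing would
  sm <- gauss_smooth3d(n, rep(smoothness, 3))
  sm <- sm / max(abs(sm))
  f <- exp(log1p(amplitude) * sm)
  f / mean(f)
}

# Rasterize one ellipsoid: returns logical array. Axes in voxels; in-plane
# rotation by theta.
ellipsoid_mask <- function(shape, center, radii, theta) {
  zz <- seq_len(shape[1]); yy <- seq_len(shape[2]); xx <- seq_len(shape[3])
  dz <- (zz - center[1]) / radii[1]
  dy <- yy - center[2]
  dx <- xx - center[3]
  ct <- cos(theta); st <- sin(theta)
  # rotated in-plane coordinates, scaled by radii
  u <- outer(dy * ct, dx * st, "+") / radii[2]       # (rows, cols)
  v <- outer(-dy * st, dx * ct, "+") / radii[3]
  plane <- u^2 + v^2                                  # (rows, cols)
  out <- array(FALSE, shape)
  for (k in seq_len(shape[1])) out[k, , ] <- plane + dz[k]^2 <= 1
  out
}

#' Generate one synthetic exam
#'
#' Fully determined by `(config$seed, index)`: the same pair always yields a
#' bit-identical exam. See [phantom_config()] for the generative model.
#'
#' @param config A [phantom_config()].
#' @param index Exam index in `1..n_exams`.
#' @return An [exam()] whose mask is the exact simulated tumor.
#' @export
generate_exam <- function(config, index) {
  stopifnot(inherits(config, "phantom_config"))
  index <- as.integer(index)
  if (index < 1 || index > config$n_exams)
    stop("index out of range", call. = FALSE)
  shape <- config$shape
  rr <- config$tumor_radius_range
  margin <- 2
  if (2 * rr[1] > min(shape[2:3]) - 2 * margin)
    stop("tumor cannot fit inside the grid", call. = FALSE)

  seed_i <- derive_seed(config$seed, "exam", index)
  with_local_seed(seed_i, {
    bg <- 0.10; tissue <- 0.35; fat <- 1.0
    truth <- array(bg, shape)
    # soft-tissue body: large in-plane ellipse through all slices
    body <- ellipsoid_mask(shape,
                           center = c((shape[1] + 1) / 2, shape[2] / 2, shape[3] / 2),
                           radii = c(shape[1], shape[2] * 0.46, shape[3] * 0.46),
                           theta = 0)
    truth[body] <- tissue
    # bright subcutaneous fat band: a few rows near the top of the body
    band_rows <- pmin(pmax(round(shape[2] * 0.12) + 0:2, 1), shape[2])
    truth[, band_rows, ] <- ifelse(truth[, band_rows, ] > bg, fat, bg)

    # tumor: 1-3 overlapping ellipsoids (lobulation)
    n_lobes <- if (config$lobulation) sample(1:3, 1) else 1L
    r_main <- runif(1, rr[1], min(rr[2], (min(shape[2:3]) - 2 * margin) / 2))
    rz_max <- max(1, (shape[1] - 2) / 2)
    rz <- runif(1, min(1, rz_max), rz_max)
    cz <- runif(1, 1 + rz, shape[1] - rz)
    cy <- runif(1, 1 + margin + r_main, shape[2] - margin - r_main)
    cx <- runif(1, 1 + margin + r_main, shape[3] - margin - r_main)
    tum <- array(FALSE, shape)
    for (l in seq_len(n_lobes)) {
      scl <- if (l == 1) 1 else runif(1, 0.4, 0.7)
      off <- if (l == 1) c(0, 0) else runif(2, -0.5, 0.5) * r_main
      ry <- r_main * scl * runif(1, 0.7, 1.0)
      rx <- r_main * scl * runif(1, 0.7, 1.0)
      cyl <- min(max(cy + off[1], 1 + ry), shape[2] - ry)
      cxl <- min(max(cx + off[2], 1 + rx), shape[3] - rx)
      tum <- tum | ellipsoid_mask(shape, c(cz, cyl, cxl),
                                  c(rz * max(scl, 0.6), ry, rx),
                                  theta = runif(1, 0, pi))
    }
    contrast <- runif(1, config$tumor_contrast_range[1], config$tumor_contrast_range[2])
    truth[tum] <- fat * contrast

    bias <- make_bias_field(shape, config$bias_amplitude, config$bias_smoothness,
                            seed = derive_seed(seed_i, "bias"))
    style <- config$site_styles[[((index - 1) %% length(config$site_styles)) + 1]]
    img <- truth * bias
    img <- style[1] + style[2] * img^style[3]
    if (config$noise_sd > 0)
      img <- img + rnorm(length(img), sd = config$noise_sd)
    dim(img) <- shape

    id <- sprintf("phantom%03d", index)
    loc <- config$location_labels[((index - 1) %% length(config$location_labels)) + 1]
    ex <- exam(image_volume(img, config$spacing, id),
               segmentation_mask(array(as.numeric(tum), shape), config$spacing, id),
               location_label = loc,
               site_tag = sprintf("site%d", ((index - 1) %% length(config$site_styles)) + 1))
    attr(ex, "truth") <- truth  # bias/noise-free reference, used by tests
    ex
  })
}

#' Generate a full phantom cohort
#'
#' @param config A [phantom_config()].
#' @return List of [exam()] objects; site styles and location labels are
#'   cycled round-robin, deterministically.
#' @export
generate_cohort <- function(config) {
  lapply(seq_len(config$n_exams), function(i) generate_exam(config, i))
}
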