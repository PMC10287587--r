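# Shared fixtures, built in code at test time.

# Small deterministic phantom cohorts (cached per options so repeated tests
# don't regenerate).
.fixture_env <- new.env(parent = emptyenv())

easy_phantom_config <- function(n_exams = 12L, seed = 42L) {
  # no bias, no noise, one identity site style, high contrast: the tumor is a
  # constant-intensity ellipsoid, segmentable by thresholding
  phantom_config(n_exams = n_exams, bias_amplitude = 0, noise_sd = 0,
                 site_styles = list(c(0, 1, 1)),
                 tumor_contrast_range = c(1.4, 1.8), seed = seed)
}

get_cohort <- function(key, config) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- generate_cohort(config)
  .fixture_env[[key]]
}

# A random binary mask array with given density.
random_mask <- function(dim_, p = 0.3) {
  array(rbinom(prod(dim_), 1, p), dim_)
}

# Brute-force confusion counting by explicit voxel loop (independent oracle).
brute_confusion <- function(pred, ref) {
  tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && ref[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1 && ref[i] == 0) fp <- fp + 1L
    else if (pred[i] == 0 && ref[i] == 0) tn <- tn + 1L
    else fn <- fn + 1L
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

# Brute-force HD95: explicit all-pairs double loop over boundary voxels.
brute_hd95 <- function(pred, ref, spacing) {
  bnd <- function(m) {
    d <- dim(m)
    out <- NULL
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (m[i, j, k] != 1) next
      nb <- c(
        if (i > 1) m[i - 1, j, k] else 0, if (i < d[1]) m[i + 1, j, k] else 0,
        if (j > 1) m[i, j - 1, k] else 0, if (j < d[2]) m[i, j + 1, k] else 0,
        if (k > 1) m[i, j, k - 1] else 0, if (k < d[3]) m[i, j, k + 1] else 0)
      if (any(nb == 0)) out <- rbind(out, c(i, j, k))
    }
    out
  }
  ba <- bnd(pred); bb <- bnd(ref)
  if (is.null(ba) || is.null(bb)) return(NA_real_)
  one_way <- function(A, B) {
    apply(A, 1, function(a) {
      min(apply(B, 1, function(b) sqrt(sum(((a - b) * spacing)^2))))
    })
  }
  pooled <- c(one_way(ba, bb), one_way(bb, ba))
  unname(quantile(pooled, 0.95, type = 7))
}
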