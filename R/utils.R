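# Internal helpers shared across modules: seeded local RNG, seed derivation,
# validation, and 2D interpolation primitives.

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministically derive a child seed < 2^31 from a parent seed and salts
# (integers or strings). Splitting one pipeline seed into independent
# per-stage streams keeps every stage reproducible in isolation.
derive_seed <- function(seed, ...) {
  h <- as.double(seed) %% 2147483647
  for (salt in list(...)) {
    if (is.character(salt)) salt <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
    h <- (h * 48271 + as.double(salt) + 1) %% 2147483647
  }
  as.integer(h)
}

stop_if_not_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Bilinear sample of a 2D matrix at fractional (row, col) coordinates
# (1-based). Coordinates outside the matrix return `fill`.
bilinear_sample <- function(mat, r, c, fill = 0) {
  nr <- nrow(mat); nc <- ncol(mat)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  out <- numeric(length(r))
  get_px <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- numeric(length(ri))
    v[ok] <- mat[cbind(ri[ok], ci[ok])]
    v[!ok] <- fill
    v
  }
  out <- (1 - fr) * (1 - fc) * get_px(r0, c0) +
    (1 - fr) * fc * get_px(r0, c0 + 1) +
    fr * (1 - fc) * get_px(r0 + 1, c0) +
    fr * fc * get_px(r0 + 1, c0 + 1)
  out
}

# Nearest-neighbour sample with zero fill outside.
nearest_sample <- function(mat, r, c, fill = 0) {
  nr <- nrow(mat); nc <- ncol(mat)
  ri <- round(r); ci <- round(c)
  ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
  v <- numeric(length(r))
  v[ok] <- mat[cbind(ri[ok], ci[ok])]
  v[!ok] <- fill
  v
}

# Resize a 2D matrix to (out_h, out_w) with pixel-center alignment.
resize2d <- function(mat, out_h, out_w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  sy <- nrow(mat) / out_h; sx <- ncol(mat) / out_w
  # output pixel centers mapped into input coordinates (1-based)
  rr <- (seq_len(out_h) - 0.5) * sy + 0.5
  cc <- (seq_len(out_w) - 0.5) * sx + 0.5
  grid_r <- rep(rr, times = out_w)
  grid_c <- rep(cc, each = out_h)
  v <- if (method == "bilinear") bilinear_sample(mat, grid_r, grid_c)
  else nearest_sample(mat, grid_r, grid_c)
  matrix(v, out_h, out_w)
}

# Separable Gaussian smoothing of a 3D array (replicate padding at edges).
gauss_smooth3d <- function(x, sigma) {
  smooth_axis <- function(a, axis, s) {
    if (s <= 0) return(a)
    rad <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-rad, rad))^2 / (2 * s^2)); k <- k / sum(k)
    d <- dim(a)
    n <- d[axis]
    idx <- lapply(seq(-rad, rad), function(off) pmin(pmax(seq_len(n) + off, 1L), n))
    out <- array(0, d)
    for (t in seq_along(k)) {
      sl <- switch(axis,
        a[idx[[t]], , , drop = FALSE],
        a[, idx[[t]], , drop = FALSE],
        a[, , idx[[t]], drop = FALSE])
      out <- out + k[t] * sl
    }
    out
  }
  if (length(sigma) == 1) sigma <- rep(sigma, 3)
  x <- smooth_axis(x, 1L, sigma[1])
  x <- smooth_axis(x, 2L, sigma[2])
  smooth_axis(x, 3L, sigma[3])
}
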