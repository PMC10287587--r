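# Layer primitives for the 2D segmentation networks. All activations are
# numeric arrays with layout (H, W, N, C); every layer provides a forward
# returning (out, cache) and a backward returning (dx, parameter grads).
# Hot 3x3 convolutions call the compiled kernels in src/conv_ops.cpp.

# column-wise broadcast helpers backed by C++ (x is an (m x C) matrix);
# sweep()'s aperm overhead dominates the training loop otherwise
col_add <- function(x, v) {
  y <- col_affine_cpp(x, rep(1, length(v)), v)
  dim(y) <- dim(x)
  y
}

conv3x3_fwd <- function(x, W, b) {
  d <- dim(x)
  y <- conv3x3_fwd_cpp(x, W, b, d[1], d[2], d[3], d[4], dim(W)[4])
  dim(y) <- c(d[1], d[2], d[3], dim(W)[4])
  y
}

conv3x3_bwd <- function(dy, x, W) {
  d <- dim(x)
  g <- conv3x3_bwd_cpp(dy, x, W, d[1], d[2], d[3], d[4], dim(W)[4])
  dim(g$dx) <- d
  dim(g$dW) <- dim(W)
  g
}

conv1x1_fwd <- function(x, W, b) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(prod(d[1:3]), d[4])
  Wm <- matrix(W, d[4], length(b))
  y <- col_add(xm %*% Wm, b)
  dim(y) <- c(d[1:3], length(b))
  y
}

conv1x1_bwd <- function(dy, x, W, nb) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(prod(d[1:3]), d[4])
  dym <- dy; dim(dym) <- c(prod(d[1:3]), nb)
  Wm <- matrix(W, d[4], nb)
  dx <- dym %*% t(Wm)
  dim(dx) <- d
  list(dx = dx, dW = array(crossprod(xm, dym), dim = c(1, 1, d[4], nb)),
       db = colSums(dym))
}

relu_fwd <- function(x) {
  y <- relu_fwd_cpp(x)
  dim(y) <- dim(x)
  y
}

# `out` is the forward output: positive exactly where the input was
relu_bwd <- function(dy, out) {
  dx <- relu_bwd_cpp(dy, out)
  dim(dx) <- dim(dy)
  dx
}

BN_EPS <- 1e-5

bn_fwd <- function(x, gamma, beta, run_mean, run_var, training, momentum = 0.9) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(prod(d[1:3]), d[4])
  if (training) {
    mu <- colMeans(xm)
    va <- pmax(colMeans(xm * xm) - mu^2, 0)
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var <- momentum * run_var + (1 - momentum) * va
  } else {
    mu <- run_mean; va <- run_var
  }
  ivar <- 1 / sqrt(va + BN_EPS)
  xhat <- col_affine_cpp(xm, ivar, -mu * ivar)
  dim(xhat) <- dim(xm)
  y <- col_affine_cpp(xhat, gamma, beta)
  dim(y) <- d
  list(out = y, cache = list(xhat = xhat, ivar = ivar, d = d, training = training),
       run_mean = run_mean, run_var = run_var)
}

bn_bwd <- function(dy, cache, gamma) {
  d <- cache$d
  m <- prod(d[1:3])
  dym <- dy; dim(dym) <- c(m, d[4])
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- col_affine_cpp(dym, gamma, numeric(length(gamma)))
  dim(dxhat) <- dim(dym)
  if (cache$training) {
    # standard batch-norm backward through the batch statistics
    t1 <- colSums(dxhat)
    t2 <- colSums(dxhat * xhat)
    dx <- col_lincomb_cpp(dxhat, xhat, cache$ivar,
                          -cache$ivar * t2 / m, -cache$ivar * t1 / m)
  } else {
    dx <- col_affine_cpp(dxhat, cache$ivar, numeric(length(gamma)))
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

maxpool2_fwd <- function(x) {
  d <- dim(x)
  p <- maxpool2_cpp(x, d[1], d[2], d[3] * d[4])
  out <- p$out
  dim(out) <- c(d[1] %/% 2L, d[2] %/% 2L, d[3], d[4])
  list(out = out, cache = list(arg = p$arg, d = d))
}

maxpool2_bwd <- function(dy, cache) {
  d <- cache$d
  dx <- maxpool2_bwd_cpp(dy, cache$arg, d[1], d[2], d[3] * d[4])
  dim(dx) <- d
  dx
}

# 2x2 stride-2 transposed convolution: W is (2, 2, Cin, Cout).
upconv2_fwd <- function(x, W, b) {
  d <- dim(x)
  Cout <- dim(W)[4]
  xm <- x; dim(xm) <- c(prod(d[1:3]), d[4])
  y <- array(0, c(2 * d[1], 2 * d[2], d[3], Cout))
  for (dy_ in 0:1) for (dx_ in 0:1) {
    Wm <- matrix(W[dy_ + 1, dx_ + 1, , ], d[4], Cout)
    t <- col_add(xm %*% Wm, b)
    dim(t) <- c(d[1], d[2], d[3], Cout)
    y[seq(1 + dy_, 2 * d[1], 2), seq(1 + dx_, 2 * d[2], 2), , ] <- t
  }
  y
}

upconv2_bwd <- function(dy, x, W) {
  d <- dim(x)
  Cout <- dim(W)[4]
  xm <- x; dim(xm) <- c(prod(d[1:3]), d[4])
  dxm <- matrix(0, prod(d[1:3]), d[4])
  dW <- array(0, dim(W))
  db <- numeric(Cout)
  for (dy_ in 0:1) for (dx_ in 0:1) {
    g <- dy[seq(1 + dy_, 2 * d[1], 2), seq(1 + dx_, 2 * d[2], 2), , , drop = FALSE]
    dim(g) <- c(prod(d[1:3]), Cout)
    Wm <- matrix(W[dy_ + 1, dx_ + 1, , ], d[4], Cout)
    dxm <- dxm + g %*% t(Wm)
    dW[dy_ + 1, dx_ + 1, , ] <- crossprod(xm, g)
    db <- db + colSums(g)
  }
  dim(dxm) <- d
  list(dx = dxm, dW = dW, db = db)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Dense per-axis factor-2 bilinear upsampling matrix (pixel-center
# convention), used by the attention gates; small enough to keep dense.
up2_matrix <- function(n) {
  U <- matrix(0, 2 * n, n)
  for (o in seq_len(2 * n)) {
    src <- (o - 0.5) / 2 - 0.5  # 0-based source coordinate
    i0 <- floor(src)
    f <- src - i0
    i0c <- min(max(i0, 0), n - 1)
    i1c <- min(max(i0 + 1, 0), n - 1)
    U[o, i0c + 1] <- U[o, i0c + 1] + (1 - f)
    U[o, i1c + 1] <- U[o, i1c + 1] + f
  }
  U
}

# Apply A along axis 1 and B along axis 2 of an (H, W, N, C) array:
# out[, , n, c] = A %*% x[, , n, c] %*% t(B).
apply_sep2d <- function(x, A, B) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1], prod(d[2:4]))
  t1 <- A %*% xm                               # (H', W*N*C)
  dim(t1) <- c(nrow(A), d[2], d[3], d[4])
  t1p <- aperm(t1, c(2, 1, 3, 4))
  dim(t1p) <- c(d[2], nrow(A) * d[3] * d[4])
  t2 <- B %*% t1p                              # (W', H'*N*C)
  dim(t2) <- c(nrow(B), nrow(A), d[3], d[4])
  aperm(t2, c(2, 1, 3, 4))
}

up2x_bilinear_fwd <- function(x) {
  d <- dim(x)
  apply_sep2d(x, up2_matrix(d[1]), up2_matrix(d[2]))
}

up2x_bilinear_bwd <- function(dy, in_h, in_w) {
  apply_sep2d(dy, t(up2_matrix(in_h)), t(up2_matrix(in_w)))
}

# ---- Additive attention gate ------------------------------------------
# skip s (H, W, N, Cs) gated by the coarser-level signal g (H/2, W/2, N, Cg):
# alpha = sigmoid(psi(relu(up2x(Wg g) + Wx s))), out = s * alpha.
attgate_fwd <- function(s, g, p) {
  pg <- conv1x1_fwd(g, p$Wg, p$bg)
  pgu <- up2x_bilinear_fwd(pg)
  px <- conv1x1_fwd(s, p$Wx, p$bx)
  z <- pgu + px
  q <- relu_fwd(z)
  a_lin <- conv1x1_fwd(q, p$Wpsi, p$bpsi)
  alpha <- sigmoid(a_lin)
  av <- as.numeric(alpha)
  out <- s * av  # broadcast over channels: (H,W,N) block recycles per channel
  list(out = out,
       cache = list(s = s, g = g, q = q, alpha = alpha, d_g = dim(g)))
}

attgate_bwd <- function(dout, cache, p) {
  s <- cache$s
  dims <- dim(s)
  Cs <- dims[4]
  av <- as.numeric(cache$alpha)
  ds_direct <- dout * av
  # d alpha = sum over skip channels of dout * s
  prod_ <- dout * s
  dim(prod_) <- c(prod(dims[1:3]), Cs)
  dalpha <- rowSums(prod_)
  dim(dalpha) <- c(dims[1:3], 1L)
  da_lin <- dalpha * cache$alpha * (1 - cache$alpha)
  gpsi <- conv1x1_bwd(da_lin, cache$q, p$Wpsi, 1L)
  dz <- relu_bwd(gpsi$dx, cache$q)
  gx <- conv1x1_bwd(dz, s, p$Wx, dim(p$Wx)[4])
  dpg <- up2x_bilinear_bwd(dz, cache$d_g[1], cache$d_g[2])
  gg <- conv1x1_bwd(dpg, cache$g, p$Wg, dim(p$Wg)[4])
  list(ds = ds_direct + gx$dx, dg = gg$dx,
       grads = list(Wg = gg$dW, bg = gg$db, Wx = gx$dW, bx = gx$db,
                    Wpsi = gpsi$dW, bpsi = gpsi$db))
}

# ---- Adam optimizer ----------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
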