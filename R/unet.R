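# 2D U-Net and attention U-Net: configuration, parameter initialization,
# forward and backward passes, and exact trainable-parameter counting.

#' U-Net configuration
#'
#' Encoder of `levels` blocks (two 3x3 convolutions, each followed by
#' batch-norm and ReLU) with 2x2 max-pooling between levels and features
#' doubling per level from `root_features`; mirrored decoder with 2x2
#' transposed-convolution upsampling and skip concatenation; final 1x1
#' convolution with sigmoid output. With `attention = TRUE` each skip passes
#' through an additive attention gate driven by the coarser-level features.
#'
#' @param levels Number of resolution levels (>= 1).
#' @param root_features Channels on the first level; doubled per level down.
#' @param in_channels,out_channels Input/output channels (both 1 for
#'   grayscale MR slices and a tumor probability map).
#' @param attention Gate the skip connections?
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(levels = 5L, root_features = 32L,
                        in_channels = 1L, out_channels = 1L,
                        attention = FALSE) {
  levels <- as.integer(levels); root_features <- as.integer(root_features)
  if (levels < 1) stop("levels must be >= 1", call. = FALSE)
  if (root_features < 1) stop("root_features must be >= 1", call. = FALSE)
  structure(list(levels = levels, root_features = root_features,
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 attention = isTRUE(attention)),
            class = "unet_config")
}

level_channels <- function(config, l) config$root_features * 2L^(l - 1L)

att_features <- function(c_skip) max(c_skip %/% 2L, 1L)

#' Count trainable parameters of a network configuration
#'
#' Exact count of trainable scalars: convolution weights and biases,
#' batch-norm scale and shift, transposed-convolution and attention-gate
#' parameters. Batch-norm running statistics are not trainable and are not
#' counted.
#'
#' @param config A [unet_config()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(config) {
  stopifnot(inherits(config, "unet_config"))
  L <- config$levels
  total <- 0
  for (l in seq_len(L)) {
    cl <- level_channels(config, l)
    cin <- if (l == 1) config$in_channels else level_channels(config, l - 1)
    total <- total + (9 * cin * cl + cl) + 2 * cl +  # conv1 + bn1
      (9 * cl * cl + cl) + 2 * cl                    # conv2 + bn2
  }
  if (L > 1) for (l in seq(L - 1, 1)) {
    cl <- level_channels(config, l)
    cb <- level_channels(config, l + 1)
    total <- total + (4 * cb * cl + cl) +            # transposed conv
      (9 * (2 * cl) * cl + cl) + 2 * cl +            # conv1 + bn1
      (9 * cl * cl + cl) + 2 * cl                    # conv2 + bn2
    if (config$attention) {
      f <- att_features(cl)
      total <- total + (cb * f + f) + (cl * f + f) + (f + 1)
    }
  }
  total + (config$root_features * config$out_channels + config$out_channels)
}

he_conv <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

#' Build (initialize) a U-Net
#'
#' He-initialized convolution weights, unit batch-norm scale, zero shifts and
#' biases; batch-norm running statistics start at mean 0 / variance 1.
#'
#' @param config A [unet_config()].
#' @param seed Integer seed for the weight initialization.
#' @return An object of class `unet`: list with `config`, `params` (flat
#'   named list of trainable arrays) and `state` (batch-norm running stats).
#' @export
build_unet <- function(config, seed = 0L) {
  stopifnot(inherits(config, "unet_config"))
  L <- config$levels
  params <- list()
  state <- list()
  with_local_seed(seed, {
    for (l in seq_len(L)) {
      cl <- level_channels(config, l)
      cin <- if (l == 1) config$in_channels else level_channels(config, l - 1)
      pre <- sprintf("enc%d", l)
      params[[paste0(pre, ".conv1.W")]] <- he_conv(3, 3, cin, cl)
      params[[paste0(pre, ".conv1.b")]] <- numeric(cl)
      params[[paste0(pre, ".bn1.gamma")]] <- rep(1, cl)
      params[[paste0(pre, ".bn1.beta")]] <- numeric(cl)
      params[[paste0(pre, ".conv2.W")]] <- he_conv(3, 3, cl, cl)
      params[[paste0(pre, ".conv2.b")]] <- numeric(cl)
      params[[paste0(pre, ".bn2.gamma")]] <- rep(1, cl)
      params[[paste0(pre, ".bn2.beta")]] <- numeric(cl)
      for (bn in c("bn1", "bn2")) {
        state[[paste0(pre, ".", bn, ".mean")]] <- numeric(cl)
        state[[paste0(pre, ".", bn, ".var")]] <- rep(1, cl)
      }
    }
    if (L > 1) for (l in seq(L - 1, 1)) {
      cl <- level_channels(config, l)
      cb <- level_channels(config, l + 1)
      pre <- sprintf("dec%d", l)
      params[[paste0(pre, ".up.W")]] <- he_conv(2, 2, cb, cl)
      params[[paste0(pre, ".up.b")]] <- numeric(cl)
      if (config$attention) {
        f <- att_features(cl)
        params[[paste0(pre, ".att.Wg")]] <- he_conv(1, 1, cb, f)
        params[[paste0(pre, ".att.bg")]] <- numeric(f)
        params[[paste0(pre, ".att.Wx")]] <- he_conv(1, 1, cl, f)
        params[[paste0(pre, ".att.bx")]] <- numeric(f)
        params[[paste0(pre, ".att.Wpsi")]] <- he_conv(1, 1, f, 1)
        params[[paste0(pre, ".att.bpsi")]] <- numeric(1)
      }
      params[[paste0(pre, ".conv1.W")]] <- he_conv(3, 3, 2 * cl, cl)
      params[[paste0(pre, ".conv1.b")]] <- numeric(cl)
      params[[paste0(pre, ".bn1.gamma")]] <- rep(1, cl)
      params[[paste0(pre, ".bn1.beta")]] <- numeric(cl)
      params[[paste0(pre, ".conv2.W")]] <- he_conv(3, 3, cl, cl)
      params[[paste0(pre, ".conv2.b")]] <- numeric(cl)
      params[[paste0(pre, ".bn2.gamma")]] <- rep(1, cl)
      params[[paste0(pre, ".bn2.beta")]] <- numeric(cl)
      for (bn in c("bn1", "bn2")) {
        state[[paste0(pre, ".", bn, ".mean")]] <- numeric(cl)
        state[[paste0(pre, ".", bn, ".var")]] <- rep(1, cl)
      }
    }
    params[["final.W"]] <- he_conv(1, 1, config$root_features, config$out_channels)
    # negative output bias: start the sigmoid near the foreground prior
    # (tumor voxels are rare), which accelerates early dice-loss descent
    params[["final.b"]] <- rep(-2, config$out_channels)
  })
  structure(list(config = config, params = params, state = state),
            class = "unet")
}

check_divisible <- function(d, levels) {
  f <- 2L^(levels - 1L)
  if (d[1] %% f != 0 || d[2] %% f != 0)
    stop(sprintf("input %dx%d not divisible by 2^(levels-1) = %d", d[1], d[2], f),
         call. = FALSE)
}

# One conv-bn-relu-conv-bn-relu block. Returns out, cache, updated state.
block_fwd <- function(x, params, state, pre, training) {
  W1 <- params[[paste0(pre, ".conv1.W")]]
  z1 <- conv3x3_fwd(x, W1, params[[paste0(pre, ".conv1.b")]])
  b1 <- bn_fwd(z1, params[[paste0(pre, ".bn1.gamma")]], params[[paste0(pre, ".bn1.beta")]],
               state[[paste0(pre, ".bn1.mean")]], state[[paste0(pre, ".bn1.var")]],
               training)
  state[[paste0(pre, ".bn1.mean")]] <- b1$run_mean
  state[[paste0(pre, ".bn1.var")]] <- b1$run_var
  a1 <- relu_fwd(b1$out)
  W2 <- params[[paste0(pre, ".conv2.W")]]
  z2 <- conv3x3_fwd(a1, W2, params[[paste0(pre, ".conv2.b")]])
  b2 <- bn_fwd(z2, params[[paste0(pre, ".bn2.gamma")]], params[[paste0(pre, ".bn2.beta")]],
               state[[paste0(pre, ".bn2.mean")]], state[[paste0(pre, ".bn2.var")]],
               training)
  state[[paste0(pre, ".bn2.mean")]] <- b2$run_mean
  state[[paste0(pre, ".bn2.var")]] <- b2$run_var
  a2 <- relu_fwd(b2$out)
  list(out = a2, state = state,
       cache = list(x = x, bn1 = b1$cache, a1 = a1, bn2 = b2$cache, a2 = a2))
}

block_bwd <- function(dout, cache, params, pre) {
  g <- list()
  d2 <- relu_bwd(dout, cache$a2)
  b2 <- bn_bwd(d2, cache$bn2, params[[paste0(pre, ".bn2.gamma")]])
  g[[paste0(pre, ".bn2.gamma")]] <- b2$dgamma
  g[[paste0(pre, ".bn2.beta")]] <- b2$dbeta
  c2 <- conv3x3_bwd(b2$dx, cache$a1, params[[paste0(pre, ".conv2.W")]])
  g[[paste0(pre, ".conv2.W")]] <- c2$dW
  g[[paste0(pre, ".conv2.b")]] <- c2$db
  d1 <- relu_bwd(c2$dx, cache$a1)
  b1 <- bn_bwd(d1, cache$bn1, params[[paste0(pre, ".bn1.gamma")]])
  g[[paste0(pre, ".bn1.gamma")]] <- b1$dgamma
  g[[paste0(pre, ".bn1.beta")]] <- b1$dbeta
  c1 <- conv3x3_bwd(b1$dx, cache$x, params[[paste0(pre, ".conv1.W")]])
  g[[paste0(pre, ".conv1.W")]] <- c1$dW
  g[[paste0(pre, ".conv1.b")]] <- c1$db
  list(dx = c1$dx, grads = g)
}

att_params <- function(params, pre) {
  list(Wg = params[[paste0(pre, ".att.Wg")]], bg = params[[paste0(pre, ".att.bg")]],
       Wx = params[[paste0(pre, ".att.Wx")]], bx = params[[paste0(pre, ".att.bx")]],
       Wpsi = params[[paste0(pre, ".att.Wpsi")]], bpsi = params[[paste0(pre, ".att.bpsi")]])
}

#' Forward pass of a U-Net
#'
#' @param net A [build_unet()] network.
#' @param x Input batch, array (H, W, N, in_channels); H and W must be
#'   divisible by `2^(levels - 1)`.
#' @param training Batch statistics (`TRUE`, updates running stats) or
#'   running statistics (`FALSE`) in the batch-norm layers?
#' @return List with `out` (probabilities in (0,1), same spatial shape),
#'   `cache` (for [unet_backward()]) and `state` (updated running stats).
#' @export
unet_forward <- function(net, x, training = FALSE) {
  config <- net$config
  d <- dim(x)
  check_divisible(d, config$levels)
  params <- net$params
  state <- net$state
  L <- config$levels
  caches <- list(enc = vector("list", L), pool = vector("list", max(L - 1, 0)),
                 dec = vector("list", max(L - 1, 0)))
  skips <- vector("list", max(L - 1, 0))
  cur <- x
  for (l in seq_len(L)) {
    if (l > 1) {
      p <- maxpool2_fwd(cur)
      caches$pool[[l - 1]] <- p$cache
      cur <- p$out
    }
    bl <- block_fwd(cur, params, state, sprintf("enc%d", l), training)
    state <- bl$state
    caches$enc[[l]] <- bl$cache
    cur <- bl$out
    if (l < L) skips[[l]] <- cur
  }
  if (L > 1) for (l in seq(L - 1, 1)) {
    pre <- sprintf("dec%d", l)
    g_sig <- cur
    u <- upconv2_fwd(cur, params[[paste0(pre, ".up.W")]], params[[paste0(pre, ".up.b")]])
    s <- skips[[l]]
    att_cache <- NULL
    if (config$attention) {
      at <- attgate_fwd(s, g_sig, att_params(params, pre))
      s <- at$out
      att_cache <- at$cache
    }
    cat_ <- c(u, s)  # channel-last layout: concatenation along channels
    dim(cat_) <- c(dim(u)[1:3], dim(u)[4] + dim(s)[4])
    bl <- block_fwd(cat_, params, state, pre, training)
    state <- bl$state
    caches$dec[[l]] <- list(block = bl$cache, att = att_cache,
                            up_in = g_sig, n_up = dim(u)[4])
    cur <- bl$out
  }
  zf <- conv1x1_fwd(cur, params[["final.W"]], params[["final.b"]])
  probs <- sigmoid(zf)
  caches$final_in <- cur
  caches$probs <- probs
  list(out = probs, cache = caches, state = state)
}

#' Backward pass of a U-Net
#'
#' Backpropagates a gradient with respect to the output probabilities through
#' the whole network (including the final sigmoid).
#'
#' @param net A [build_unet()] network.
#' @param cache The cache returned by [unet_forward()] with `training = TRUE`.
#' @param dprobs Gradient of the loss w.r.t. the output probabilities.
#' @return Named list of gradients matching `net$params`.
#' @export
unet_backward <- function(net, cache, dprobs) {
  config <- net$config
  params <- net$params
  L <- config$levels
  grads <- list()
  p <- cache$probs
  dz <- dprobs * p * (1 - p)
  cf <- conv1x1_bwd(dz, cache$final_in, params[["final.W"]], config$out_channels)
  grads[["final.W"]] <- cf$dW
  grads[["final.b"]] <- cf$db
  dcur <- cf$dx
  dskips <- vector("list", max(L - 1, 0))
  if (L > 1) for (l in seq(1, L - 1)) {
    pre <- sprintf("dec%d", l)
    dc <- cache$dec[[l]]
    bl <- block_bwd(dcur, dc$block, params, pre)
    grads <- c(grads, bl$grads)
    n_up <- dc$n_up
    du <- bl$dx[, , , seq_len(n_up), drop = FALSE]
    ds <- bl$dx[, , , n_up + seq_len(dim(bl$dx)[4] - n_up), drop = FALSE]
    dg_att <- 0
    if (config$attention) {
      ab <- attgate_bwd(ds, dc$att, att_params(params, pre))
      ds <- ab$ds
      dg_att <- ab$dg
      for (nm in names(ab$grads)) grads[[paste0(pre, ".att.", nm)]] <- ab$grads[[nm]]
    }
    ub <- upconv2_bwd(du, dc$up_in, params[[paste0(pre, ".up.W")]])
    grads[[paste0(pre, ".up.W")]] <- ub$dW
    grads[[paste0(pre, ".up.b")]] <- ub$db
    dskips[[l]] <- ds
    dcur <- ub$dx + dg_att
  }
  for (l in seq(L, 1)) {
    bl <- block_bwd(dcur, cache$enc[[l]], params, sprintf("enc%d", l))
    grads <- c(grads, bl$grads)
    dcur <- bl$dx
    if (l > 1) {
      # gradient flows back through the pool to the level above, where the
      # skip branch rejoins
      dcur <- maxpool2_bwd(dcur, cache$pool[[l - 1]])
      if (!is.null(dskips[[l - 1]])) dcur <- dcur + dskips[[l - 1]]
    }
  }
  grads
}
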