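#' Network architecture configuration
#'
#' A 3D patch-based encoder-decoder (U-Net style) segmentation network. Each
#' encoder level applies two 3x3x3 convolutions with instance normalization
#' and PReLU activations; levels after the first downsample spatially by
#' \code{stride} through a strided first convolution. Decoder levels upsample
#' by nearest-neighbour, concatenate the matching encoder skip, and apply the
#' same double-convolution block. A final 1x1x1 convolution and sigmoid
#' produce one probability channel, so the output spatial shape equals the
#' input shape.
#'
#' @param in_channels Input channels (3: T1 pre, T1 post, FLAIR).
#' @param encoder_filters Filters per encoder level (default
#'   32, 64, 128, 256, 512).
#' @param decoder_filters Filters per decoder stage, deepest first (default
#'   the reverse of \code{encoder_filters}); the first entry is the
#'   bottleneck width and must equal the last encoder entry.
#' @param stride Spatial downsampling factor per level (default 2).
#' @param out_channels Output channels (1 probability map).
#' @return An object of class \code{network_config}.
#' @export
network_config <- function(in_channels = 3L,
                           encoder_filters = c(32L, 64L, 128L, 256L, 512L),
                           decoder_filters = rev(encoder_filters),
                           stride = 2L,
                           out_channels = 1L) {
  if (length(encoder_filters) != length(decoder_filters)) {
    stop("encoder_filters and decoder_filters must have equal length",
         call. = FALSE)
  }
  if (decoder_filters[1] != encoder_filters[length(encoder_filters)]) {
    stop("the first decoder width is the bottleneck and must equal the last encoder width",
         call. = FALSE)
  }
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  structure(list(
    in_channels = as.integer(in_channels),
    encoder_filters = as.integer(encoder_filters),
    decoder_filters = as.integer(decoder_filters),
    stride = as.integer(stride),
    out_channels = as.integer(out_channels)
  ), class = "network_config")
}

# He-style initialization for a (k^3*Cin x Cout) weight matrix.
#' @noRd
init_conv <- function(cin, cout, k, stride) {
  fan_in <- k^3 * cin
  list(W = matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout),
       b = numeric(cout), k = as.integer(k), stride = as.integer(stride))
}

#' Build a segmentation model
#'
#' Initializes all convolution weights (He-style Gaussian scaled by fan-in)
#' and PReLU slopes (0.25) for the architecture described by the config.
#'
#' @param config A [network_config()].
#' @param seed Optional integer seed for reproducible initialization.
#' @return An object of class \code{celseg_model}.
#' @export
build_model <- function(config = network_config(), seed = NULL) {
  stopifnot(inherits(config, "network_config"))
  if (!is.null(seed)) set.seed(seed)
  L <- length(config$encoder_filters)
  ef <- config$encoder_filters
  df <- rev(config$decoder_filters)  # df[j]: width of decoder level j (df[L] = bottleneck)
  enc <- vector("list", L)
  cin <- config$in_channels
  for (i in seq_len(L)) {
    s <- if (i == 1) 1L else config$stride
    enc[[i]] <- list(
      conv1 = init_conv(cin, ef[i], 3L, s),
      alpha1 = rep(0.25, ef[i]),
      conv2 = init_conv(ef[i], ef[i], 3L, 1L),
      alpha2 = rep(0.25, ef[i])
    )
    cin <- ef[i]
  }
  dec <- vector("list", max(L - 1, 0))
  below <- ef[L]
  for (j in rev(seq_len(L - 1))) {
    dec[[j]] <- list(
      conv1 = init_conv(below + ef[j], df[j], 3L, 1L),
      alpha1 = rep(0.25, df[j]),
      conv2 = init_conv(df[j], df[j], 3L, 1L),
      alpha2 = rep(0.25, df[j])
    )
    below <- df[j]
  }
  head_in <- if (L > 1) df[1] else ef[1]
  structure(list(
    config = config,
    enc = enc, dec = dec,
    head = init_conv(head_in, config$out_channels, 1L, 1L)
  ), class = "celseg_model")
}

#' @noRd
conv_fwd <- function(x, ly) {
  cpp_conv3d_forward(x, dim(x), ly$W, ly$b, ly$k, ly$stride)
}

#' @noRd
instnorm_fwd <- function(x, eps = 1e-5) {
  dm <- dim(x)
  n <- prod(dm[1:3])
  xm <- matrix(x, n, dm[4])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  inv <- 1 / sqrt(colMeans(xc * xc) + eps)
  xhat <- sweep(xc, 2, inv, `*`)
  list(y = array(xhat, dm), xhat = xhat, inv = inv)
}

#' @noRd
instnorm_bwd <- function(dy, cache) {
  dm <- dim(dy)
  n <- prod(dm[1:3])
  dym <- matrix(dy, n, dm[4])
  m1 <- colMeans(dym)
  m2 <- colMeans(dym * cache$xhat)
  dx <- sweep(dym, 2, m1) - sweep(cache$xhat, 2, m2, `*`)
  array(sweep(dx, 2, cache$inv, `*`), dm)
}

#' @noRd
prelu_fwd <- function(x, alpha) {
  dm <- dim(x)
  xm <- matrix(x, prod(dm[1:3]), dm[4])
  y <- pmax(xm, 0) + sweep(pmin(xm, 0), 2, alpha, `*`)
  array(y, dm)
}

#' @noRd
prelu_bwd <- function(dy, x, alpha) {
  dm <- dim(x)
  n <- prod(dm[1:3])
  xm <- matrix(x, n, dm[4])
  dym <- matrix(dy, n, dm[4])
  neg <- xm < 0
  dx <- dym * (!neg) + sweep(dym * neg, 2, alpha, `*`)
  dalpha <- colSums(dym * xm * neg)
  list(dx = array(dx, dm), dalpha = dalpha)
}

#' @noRd
upsample_fwd <- function(x, f = 2L) {
  dm <- dim(x)
  x[rep(seq_len(dm[1]), each = f), rep(seq_len(dm[2]), each = f),
    rep(seq_len(dm[3]), each = f), , drop = FALSE]
}

#' @noRd
upsample_bwd <- function(dy, f = 2L) {
  dm <- dim(dy)
  d <- dm[1:3] / f
  out <- array(0, c(d, dm[4]))
  for (a in seq_len(f)) for (b in seq_len(f)) for (cc in seq_len(f)) {
    out <- out + dy[seq(a, dm[1], by = f), seq(b, dm[2], by = f),
                    seq(cc, dm[3], by = f), , drop = FALSE]
  }
  out
}

# Double-convolution block: conv -> IN -> PReLU -> conv -> IN -> PReLU.
#' @noRd
block_fwd <- function(x, blk, want_cache) {
  c1 <- conv_fwd(x, blk$conv1)
  n1 <- instnorm_fwd(c1)
  a1 <- prelu_fwd(n1$y, blk$alpha1)
  c2 <- conv_fwd(a1, blk$conv2)
  n2 <- instnorm_fwd(c2)
  a2 <- prelu_fwd(n2$y, blk$alpha2)
  cache <- if (want_cache) {
    list(x = x, n1 = n1[c("xhat", "inv")], a1 = a1, n2 = n2[c("xhat", "inv")],
         dims1 = dim(x), dims2 = dim(a1))
  } else NULL
  list(y = a2, cache = cache)
}

#' @noRd
block_bwd <- function(dy, blk, cache) {
  n2y <- array(cache$n2$xhat, dim(dy))
  p2 <- prelu_bwd(dy, n2y, blk$alpha2)
  dn2 <- instnorm_bwd(p2$dx, cache$n2)
  g2 <- cpp_conv3d_backward_w(cache$a1, cache$dims2, dn2, ncol(blk$conv2$W),
                              blk$conv2$k, blk$conv2$stride)
  da1 <- cpp_conv3d_backward_x(dn2, cache$dims2, blk$conv2$W,
                               blk$conv2$k, blk$conv2$stride)
  n1y <- array(cache$n1$xhat, dim(da1))
  p1 <- prelu_bwd(da1, n1y, blk$alpha1)
  dn1 <- instnorm_bwd(p1$dx, cache$n1)
  g1 <- cpp_conv3d_backward_w(cache$x, cache$dims1, dn1, ncol(blk$conv1$W),
                              blk$conv1$k, blk$conv1$stride)
  dx <- cpp_conv3d_backward_x(dn1, cache$dims1, blk$conv1$W,
                              blk$conv1$k, blk$conv1$stride)
  list(dx = dx,
       grads = list(conv1 = list(W = g1$dW, b = g1$db), alpha1 = p1$dalpha,
                    conv2 = list(W = g2$dW, b = g2$db), alpha2 = p2$dalpha))
}

#' Forward pass of the segmentation network
#'
#' @param model A \code{celseg_model}.
#' @param x Numeric 4D array (edge, edge, edge, in_channels); the edge must
#'   be divisible by \code{stride^(levels - 1)}.
#' @param want_cache Logical; keep intermediate activations for
#'   [unet_backward()].
#' @return List with \code{prob} (3D probability array in (0, 1)) and, when
#'   requested, \code{cache}.
#' @export
unet_forward <- function(model, x, want_cache = FALSE) {
  cfg <- model$config
  L <- length(cfg$encoder_filters)
  if (length(dim(x)) != 4 || dim(x)[4] != cfg$in_channels) {
    stop(sprintf("input must be a 4D array with %d channels", cfg$in_channels),
         call. = FALSE)
  }
  edge <- dim(x)[1]
  if (edge %% cfg$stride^(L - 1) != 0) {
    stop(sprintf("input edge %d must be divisible by %d", edge,
                 cfg$stride^(L - 1)), call. = FALSE)
  }
  skips <- vector("list", L)
  enc_cache <- vector("list", L)
  h <- x
  for (i in seq_len(L)) {
    bf <- block_fwd(h, model$enc[[i]], want_cache)
    skips[[i]] <- bf$y
    enc_cache[[i]] <- bf$cache
    h <- bf$y
  }
  dec_cache <- vector("list", max(L - 1, 0))
  cat_split <- integer(max(L - 1, 0))
  for (j in rev(seq_len(L - 1))) {
    up <- upsample_fwd(h, cfg$stride)
    cat_split[j] <- dim(up)[4]
    dm <- dim(up)
    cat4 <- array(0, c(dm[1:3], dm[4] + dim(skips[[j]])[4]))
    cat4[, , , seq_len(dm[4])] <- up
    cat4[, , , dm[4] + seq_len(dim(skips[[j]])[4])] <- skips[[j]]
    bf <- block_fwd(cat4, model$dec[[j]], want_cache)
    if (want_cache) bf$cache$up_dims <- dim(h)
    dec_cache[[j]] <- bf$cache
    h <- bf$y
  }
  logits <- conv_fwd(h, model$head)
  prob <- 1 / (1 + exp(-logits))
  out <- list(prob = array(prob, dim(prob)[1:3]))
  if (want_cache) {
    out$cache <- list(enc = enc_cache, dec = dec_cache, head_in = h,
                      cat_split = cat_split, prob = prob)
  }
  out
}

#' Backward pass of the segmentation network
#'
#' Backpropagates the gradient of a scalar loss with respect to the output
#' probability map through the whole network.
#'
#' @param model A \code{celseg_model}.
#' @param cache Cache returned by [unet_forward()] with
#'   \code{want_cache = TRUE}.
#' @param dprob Gradient of the loss w.r.t. the probability map (3D array).
#' @return Parameter gradients mirroring the model structure (\code{enc},
#'   \code{dec}, \code{head}).
#' @export
unet_backward <- function(model, cache, dprob) {
  cfg <- model$config
  L <- length(cfg$encoder_filters)
  prob <- cache$prob
  dlogits <- array(dprob, dim(prob)) * prob * (1 - prob)
  hg <- cpp_conv3d_backward_w(cache$head_in, dim(cache$head_in), dlogits,
                              ncol(model$head$W), model$head$k,
                              model$head$stride)
  dh <- cpp_conv3d_backward_x(dlogits, dim(cache$head_in), model$head$W,
                              model$head$k, model$head$stride)
  grads <- list(enc = vector("list", L), dec = vector("list", max(L - 1, 0)),
                head = list(W = hg$dW, b = hg$db))
  dskip <- vector("list", L)
  for (j in seq_len(L - 1)) {
    bb <- block_bwd(dh, model$dec[[j]], cache$dec[[j]])
    grads$dec[[j]] <- bb$grads
    n_up <- cache$cat_split[j]
    d_up <- bb$dx[, , , seq_len(n_up), drop = FALSE]
    dskip[[j]] <- bb$dx[, , , -seq_len(n_up), drop = FALSE]
    dh <- upsample_bwd(d_up, cfg$stride)
  }
  for (i in rev(seq_len(L))) {
    if (i < L) dh <- dh + dskip[[i]]
    bb <- block_bwd(dh, model$enc[[i]], cache$enc[[i]])
    grads$enc[[i]] <- bb$grads
    dh <- bb$dx
  }
  grads
}

#' Predict probability maps for a batch of patches
#'
#' Runs the network in inference mode. No thresholding is applied.
#'
#' @param model A \code{celseg_model}.
#' @param patches A single 4D array (edge^3 x channels) or a list of them;
#'   \code{cel_patch} objects are accepted and their \code{channels} used.
#' @return A 3D probability array, or a list of them for list input.
#' @export
predict_patch <- function(model, patches) {
  single <- !is.list(patches) || inherits(patches, "cel_patch")
  if (single) patches <- list(patches)
  out <- lapply(patches, function(p) {
    x <- if (inherits(p, "cel_patch")) p$channels else p
    if (length(dim(x)) != 4 || dim(x)[4] != model$config$in_channels) {
      stop(sprintf("patch must have %d channels", model$config$in_channels),
           call. = FALSE)
    }
    unet_forward(model, x)$prob
  })
  if (single) out[[1]] else out
}
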