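# Network assembly: 3D U-net baseline, DUnet (dilated dense block on the
# middle skip connection) and ResDUnet (every pair of path convolutions
# wrapped in a residual unit).
#
# All three variants share one skeleton with exactly three 2x2x2 max
# poolings and three 4x4x4 stride-2 transposed convolutions. The feature
# maps before the first and third poolings are concatenated directly to the
# expanding path; the maps before the second pooling pass through the
# dilated dense block first (for the plain U-net they are concatenated
# directly, which is the ablation the paper compares against).

#' Architecture hyperparameters for the segmentation networks
#'
#' @param variant `"unet3d"`, `"dunet"` or `"resdunet"`.
#' @param in_channels number of input modalities (e.g. 2 for T1w + T2w).
#' @param num_classes number of label categories K, background included.
#' @param base_channels kernels at the first resolution level; the default
#'   schedule doubles per level.
#' @param channel_schedule optional length-4 integer vector: kernels at the
#'   three resolution levels plus the bottom. Overrides `base_channels`.
#' @param dense_layers number of dilated convolutions L in the dense block.
#' @param growth kernels added by each dense-block layer (defaults to the
#'   level-2 channel count).
#' @param dilation_schedule dilation rate per dense-block layer; default
#'   `2^(0:(L-1))`, i.e. rates 1, 2, 4 for L = 3.
#' @param dropout_rate dropout probability after each dense-block
#'   convolution (applied in training mode only).
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(variant = c("dunet", "unet3d", "resdunet"),
                         in_channels = 2L, num_classes = 6L,
                         base_channels = 32L, channel_schedule = NULL,
                         dense_layers = 3L, growth = NULL,
                         dilation_schedule = NULL, dropout_rate = 0.5) {
  variant <- match.arg(variant)
  if (is.null(channel_schedule))
    channel_schedule <- base_channels * c(1L, 2L, 4L, 8L)
  if (length(channel_schedule) != 4L || any(channel_schedule < 1))
    stop("'channel_schedule' must give positive kernel counts for 3 levels + bottom")
  if (is.null(dilation_schedule)) dilation_schedule <- 2L^(seq_len(dense_layers) - 1L)
  if (length(dilation_schedule) != dense_layers)
    stop("'dilation_schedule' length must equal 'dense_layers'")
  if (is.null(growth)) growth <- channel_schedule[2L]
  if (dropout_rate < 0 || dropout_rate >= 1) stop("'dropout_rate' must be in [0, 1)")
  if (in_channels < 1L || num_classes < 1L) stop("channel counts must be positive")
  structure(list(variant = variant,
                 in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 channel_schedule = as.integer(channel_schedule),
                 dense_layers = as.integer(dense_layers),
                 growth = as.integer(growth),
                 dilation_schedule = as.integer(dilation_schedule),
                 dropout_rate = dropout_rate),
            class = "network_spec")
}

## ---- composite units ----

# conv -> BN -> ReLU
make_cbr <- function(net, c_in, c_out, k = 3L, rate = 1L) {
  u <- list(conv = reg_layer(net, conv_layer(c_in, c_out, k = k, rate = rate)),
            bn = reg_layer(net, bn_layer(c_out)),
            relu = new_layer("relu"))
  u
}
cbr_fwd <- function(u, x, training) {
  relu_fwd(u$relu, bn_fwd(u$bn, conv_fwd(u$conv, x, training), training),
           training)
}
cbr_bwd <- function(u, gy) {
  conv_bwd(u$conv, bn_bwd(u$bn, relu_bwd(u$relu, gy)))
}

# A pair of 3x3x3 convolutions; with residual = TRUE the pair becomes a
# post-activation residual unit: ReLU(BN2(conv2(ReLU(BN1(conv1 x)))) + sc(x)),
# sc = identity, or a 1x1x1 projection when channel counts differ.
make_pair <- function(net, c_in, c_out, residual = FALSE) {
  p <- list(c_in = c_in, c_out = c_out, residual = residual,
            u1 = make_cbr(net, c_in, c_out),
            conv2 = reg_layer(net, conv_layer(c_out, c_out)),
            bn2 = reg_layer(net, bn_layer(c_out)),
            relu2 = new_layer("relu"))
  if (residual && c_in != c_out)
    p$proj <- reg_layer(net, conv_layer(c_in, c_out, k = 1L))
  p
}
pair_fwd <- function(p, x, training) {
  h <- bn_fwd(p$bn2, conv_fwd(p$conv2, cbr_fwd(p$u1, x, training), training),
              training)
  if (p$residual) {
    sc <- if (is.null(p$proj)) x else conv_fwd(p$proj, x, training)
    h <- h + sc
  }
  relu_fwd(p$relu2, h, training)
}
pair_bwd <- function(p, gy) {
  gh <- relu_bwd(p$relu2, gy)
  gx <- cbr_bwd(p$u1, conv_bwd(p$conv2, bn_bwd(p$bn2, gh)))
  if (p$residual) {
    gsc <- if (is.null(p$proj)) gh else conv_bwd(p$proj, gh)
    gx <- gx + gsc
  }
  gx
}

# Dilated dense block: L stride-1 3x3x3 dilated convolutions, each followed
# by BN, ReLU and dropout; layer i sees the concatenation of the block input
# and all earlier layer outputs; the block emits the concatenation of the
# input with every layer output (C + L*g channels).
make_dense_block <- function(net, c_in, L, growth, rates, dropout_rate) {
  layers <- vector("list", L)
  for (i in seq_len(L)) {
    ci <- c_in + (i - 1L) * growth
    layers[[i]] <- list(
      u = make_cbr(net, ci, growth, rate = rates[i]),
      drop = new_layer("dropout", p = dropout_rate),
      c_in = ci)
  }
  list(layers = layers, c_in = c_in, L = L, growth = growth,
       c_out = c_in + L * growth)
}
dense_fwd <- function(db, x, training) {
  feats <- list(x)
  for (i in seq_len(db$L)) {
    li <- db$layers[[i]]
    xi <- if (length(feats) == 1L) x else do.call(cat_channels, feats)
    oi <- dropout_fwd(li$drop, cbr_fwd(li$u, xi, training), training)
    feats[[i + 1L]] <- oi
  }
  do.call(cat_channels, feats)
}
dense_bwd <- function(db, gy) {
  chans <- c(db$c_in, rep(db$growth, db$L))
  g <- split_channels(gy, chans)  # grads for [input, out1, ..., outL]
  for (i in rev(seq_len(db$L))) {
    li <- db$layers[[i]]
    gi <- cbr_bwd(li$u, dropout_bwd(li$drop, g[[i + 1L]]))
    # gi distributes over the concatenated inputs of layer i
    parts <- split_channels(gi, chans[seq_len(i)])
    for (j in seq_len(i)) g[[j]] <- g[[j]] + parts[[j]]
  }
  g[[1L]]
}

reg_layer <- function(net, l) {
  net$layers[[length(net$layers) + 1L]] <- l
  l
}

## ---- network construction ----

#' Build a segmentation network from a spec
#'
#' @param spec a [network_spec()].
#' @param seed optional integer; seeds the He-normal weight initialization.
#' @return an object of class `ddu_network` (an environment holding all
#'   layers and topology metadata).
#' @export
build_network <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  if (!is.null(seed)) set.seed(seed)
  f <- spec$channel_schedule
  res <- spec$variant == "resdunet"
  dense <- spec$variant %in% c("dunet", "resdunet")
  net <- new.env(parent = emptyenv())
  net$spec <- spec
  net$layers <- list()
  m <- list()
  m$enc1 <- make_pair(net, spec$in_channels, f[1], res)
  m$pool1 <- pool_layer()
  m$enc2 <- make_pair(net, f[1], f[2], res)
  m$pool2 <- pool_layer()
  m$enc3 <- make_pair(net, f[2], f[3], res)
  m$pool3 <- pool_layer()
  m$bottom <- make_pair(net, f[3], f[4], res)
  skip2_ch <- if (dense) f[2] + spec$dense_layers * spec$growth else f[2]
  if (dense)
    m$dense <- make_dense_block(net, f[2], spec$dense_layers, spec$growth,
                                spec$dilation_schedule, spec$dropout_rate)
  m$up3 <- reg_layer(net, deconv_layer(f[4], f[3]))
  m$dec3 <- make_pair(net, f[3] + f[3], f[3], res)
  m$up2 <- reg_layer(net, deconv_layer(f[3], f[2]))
  m$dec2 <- make_pair(net, f[2] + skip2_ch, f[2], res)
  m$up1 <- reg_layer(net, deconv_layer(f[2], f[1]))
  m$dec1 <- make_pair(net, f[1] + f[1], f[1], res)
  m$final <- reg_layer(net, conv_layer(f[1], spec$num_classes, k = 1L))
  net$m <- m
  # expected channel count after every named stage (shape audit)
  net$schedule <- c(enc1 = f[1], enc2 = f[2], enc3 = f[3], bottom = f[4],
                    skip2 = skip2_ch,
                    cat3 = f[3] + f[3], dec3 = f[3],
                    cat2 = f[2] + skip2_ch, dec2 = f[2],
                    cat1 = f[1] + f[1], dec1 = f[1],
                    out = spec$num_classes)
  for (l in net$layers) zero_layer_grads(l)
  class(net) <- "ddu_network"
  net
}

chk <- function(x, net, stage) {
  if (dim(x)[4L] != net$schedule[[stage]])
    stop(sprintf("channel audit failed at '%s': got %d, expected %d",
                 stage, dim(x)[4L], net$schedule[[stage]]))
  x
}

#' Forward pass of a segmentation network
#'
#' @param net a [build_network()] result.
#' @param x 5D array (D, H, W, C, B); spatial dims must be divisible by 8
#'   (three stride-2 poolings) and C must equal the spec's `in_channels`.
#' @param training logical; enables batch-statistics BN and dropout, and
#'   caches intermediates for [network_backward()].
#' @return 5D array (D, H, W, K, B) of per-class scores (logits).
#' @export
network_forward <- function(net, x, training = FALSE) {
  d <- dim(x)
  if (length(d) != 5L) stop("input must be a 5D (D,H,W,C,B) array")
  if (d[4L] != net$spec$in_channels)
    stop(sprintf("input has %d channels; network expects %d", d[4L],
                 net$spec$in_channels))
  if (any(d[1:3] %% 8L != 0L))
    stop("spatial dims must be divisible by 8 (three stride-2 poolings)")
  m <- net$m
  tr <- training
  s1 <- chk(pair_fwd(m$enc1, x, tr), net, "enc1")
  s2 <- chk(pair_fwd(m$enc2, pool_fwd(m$pool1, s1, tr), tr), net, "enc2")
  s3 <- chk(pair_fwd(m$enc3, pool_fwd(m$pool2, s2, tr), tr), net, "enc3")
  bt <- chk(pair_fwd(m$bottom, pool_fwd(m$pool3, s3, tr), tr), net, "bottom")
  u3 <- deconv_fwd(m$up3, bt, tr)
  d3 <- chk(pair_fwd(m$dec3, chk(cat_channels(u3, s3), net, "cat3"), tr),
            net, "dec3")
  u2 <- deconv_fwd(m$up2, d3, tr)
  k2 <- if (!is.null(m$dense)) dense_fwd(m$dense, s2, tr) else s2
  chk(k2, net, "skip2")
  d2 <- chk(pair_fwd(m$dec2, chk(cat_channels(u2, k2), net, "cat2"), tr),
            net, "dec2")
  u1 <- deconv_fwd(m$up1, d2, tr)
  d1 <- chk(pair_fwd(m$dec1, chk(cat_channels(u1, s1), net, "cat1"), tr),
            net, "dec1")
  chk(conv_fwd(m$final, d1, tr), net, "out")
}

# Backward pass; network_forward(..., training = TRUE) must have run first.
# Accumulates parameter gradients in place and returns the input gradient.
network_backward <- function(net, gout) {
  m <- net$m
  f <- net$spec$channel_schedule
  skip2_ch <- net$schedule[["skip2"]]
  g_d1 <- conv_bwd(m$final, gout)
  g_cat1 <- pair_bwd(m$dec1, g_d1)
  sp <- split_channels(g_cat1, c(f[1], f[1]))
  g_d2 <- deconv_bwd(m$up1, sp[[1]])
  g_s1a <- sp[[2]]
  g_cat2 <- pair_bwd(m$dec2, g_d2)
  sp <- split_channels(g_cat2, c(f[2], skip2_ch))
  g_d3 <- deconv_bwd(m$up2, sp[[1]])
  g_s2a <- if (!is.null(m$dense)) dense_bwd(m$dense, sp[[2]]) else sp[[2]]
  g_cat3 <- pair_bwd(m$dec3, g_d3)
  sp <- split_channels(g_cat3, c(f[3], f[3]))
  g_bt <- deconv_bwd(m$up3, sp[[1]])
  g_s3a <- sp[[2]]
  g_s3 <- pool_bwd(m$pool3, pair_bwd(m$bottom, g_bt)) + g_s3a
  g_s2 <- pool_bwd(m$pool2, pair_bwd(m$enc3, g_s3)) + g_s2a
  g_s1 <- pool_bwd(m$pool1, pair_bwd(m$enc2, g_s2)) + g_s1a
  pair_bwd(m$enc1, g_s1)
}

#' Number of trainable parameters
#' @param net a `ddu_network`.
#' @return integer count of trainable scalars (conv/deconv weights and
#'   biases, BN scales and shifts).
#' @export
n_parameters <- function(net) {
  sum(vapply(net$layers, function(l) {
    if (!layer_trainable(l)) return(0L)
    sum(vapply(l$par_names, function(p) length(get(p, envir = l)), integer(1)))
  }, integer(1)))
}

#' Channel bookkeeping audit
#'
#' Runs a forward pass on a zero input and returns the expected channel
#' count at every named stage; the pass itself errors if any concatenation
#' disagrees with the configured schedule.
#'
#' @param net a `ddu_network`.
#' @param size spatial side length of the probe input (divisible by 8).
#' @return data.frame with columns `stage` and `channels`.
#' @export
channel_audit <- function(net, size = 8L) {
  x <- array(0, c(size, size, size, net$spec$in_channels, 1L))
  invisible(network_forward(net, x, training = FALSE))
  data.frame(stage = names(net$schedule),
             channels = as.integer(net$schedule), row.names = NULL)
}

## ---- checkpointing ----

network_state <- function(net) {
  lapply(net$layers, function(l) {
    nms <- c(l$par_names, intersect(c("run_mean", "run_var"), ls(l)))
    if (is.null(nms)) return(NULL)
    mget(nms, envir = l)
  })
}

set_network_state <- function(net, state) {
  stopifnot(length(state) == length(net$layers))
  for (i in seq_along(state)) {
    if (is.null(state[[i]])) next
    for (nm in names(state[[i]])) assign(nm, state[[i]][[nm]], envir = net$layers[[i]])
  }
  invisible(net)
}

#' Save / load a network checkpoint
#'
#' The checkpoint is a single file embedding the [network_spec()] and all
#' weights and batch-norm running statistics, so a restored network
#' reproduces eval-mode outputs exactly.
#'
#' @param net a `ddu_network`.
#' @param path file path.
#' @param extra optional list stored alongside (e.g. the training bounding
#'   box and histogram-matching reference).
#' @export
save_checkpoint <- function(net, path, extra = list()) {
  saveRDS(list(spec = net$spec, state = network_state(net), extra = extra),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()` returns a list with elements `net` and
#'   `extra`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- build_network(ck$spec)
  set_network_state(net, ck$state)
  list(net = net, extra = ck$extra)
}
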