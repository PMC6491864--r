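# Primitive trainable layers with explicit forward/backward passes.
#
# Feature maps are 5D arrays with dim (D, H, W, C, B). Convolutions are
# GEMMs on im2col-unrolled neighbourhoods (see src/kernels.cpp); the
# transposed convolution is the adjoint pair: forward through col2im,
# backward through im2col. Layers are environments so parameters, gradient
# accumulators and optimizer state can be updated in place.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(paste0("layer_", type), "ddu_layer")
  e
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

# channel-last view helpers: (D,H,W,C,B) <-> (D,H,W,B,C)
to_clast <- function(x) aperm(x, c(1L, 2L, 3L, 5L, 4L))
from_clast <- function(x) aperm(x, c(1L, 2L, 3L, 5L, 4L))

# matrix view with voxels*batch as rows, channels as columns
as_channel_mat <- function(x) {
  d <- dim(x)
  matrix(to_clast(x), ncol = d[4L])
}
from_channel_mat <- function(m, d) {
  from_clast(array(m, dim = c(d[1:3], d[5L], d[4L])))
}

## ---- convolution (stride 1, zero padding preserves spatial dims) ----

conv_layer <- function(c_in, c_out, k = 3L, rate = 1L, pad = NULL) {
  k <- as.integer(k); rate <- as.integer(rate)
  if (is.null(pad)) pad <- as.integer(rate * (k - 1L) / 2L)
  new_layer("conv",
            c_in = c_in, c_out = c_out, k = k, rate = rate, pad = as.integer(pad),
            W = he_init(c_out, c_in * k^3, fan_in = c_in * k^3),
            b = numeric(c_out),
            par_names = c("W", "b"))
}

conv_fwd <- function(l, x, training = TRUE) {
  d <- dim(x)
  stopifnot(d[4L] == l$c_in)
  cols <- .im2col3d(x, as.integer(d), l$k, 1L, l$rate, l$pad)
  y <- l$W %*% cols + l$b
  if (training) l$cache <- list(cols = cols, dims_in = as.integer(d))
  from_clast(array(t(y), dim = c(d[1:3], d[5L], l$c_out)))
}

conv_bwd <- function(l, gy) {
  d <- dim(gy)
  gm <- t(matrix(to_clast(gy), ncol = l$c_out))      # c_out x (N*B)
  l$gW <- l$gW + gm %*% t(l$cache$cols)
  l$gb <- l$gb + rowSums(gm)
  gcols <- crossprod(l$W, gm)
  gx <- .col2im3d(gcols, l$cache$dims_in, l$k, 1L, l$rate, l$pad)
  l$cache <- NULL
  gx
}

## ---- transposed convolution (kernel 4, stride 2, pad 1: exact 2x) ----

deconv_layer <- function(c_in, c_out, k = 4L, stride = 2L, pad = 1L) {
  k <- as.integer(k)
  new_layer("deconv",
            c_in = c_in, c_out = c_out, k = k, stride = as.integer(stride),
            pad = as.integer(pad),
            W = he_init(c_in, c_out * k^3, fan_in = c_in * k^3 / stride^3),
            b = numeric(c_out),
            par_names = c("W", "b"))
}

deconv_fwd <- function(l, x, training = TRUE) {
  d <- dim(x)
  stopifnot(d[4L] == l$c_in)
  xm <- t(matrix(to_clast(x), ncol = l$c_in))        # c_in x (n*B)
  big <- as.integer(c(d[1:3] * l$stride, l$c_out, d[5L]))
  cols <- crossprod(l$W, xm)                         # (c_out*k^3) x (n*B)
  y <- .col2im3d(cols, big, l$k, l$stride, 1L, l$pad)
  nb <- prod(big[1:3])
  y <- y + rep(rep(l$b, each = nb), times = d[5L])
  if (training) l$cache <- list(xm = xm, dims_in = as.integer(d), dims_out = big)
  y
}

deconv_bwd <- function(l, gy) {
  G <- .im2col3d(gy, l$cache$dims_out, l$k, l$stride, 1L, l$pad)
  l$gW <- l$gW + l$cache$xm %*% t(G)
  l$gb <- l$gb + colSums(as_channel_mat(gy))
  gxm <- l$W %*% G                                   # c_in x (n*B)
  d <- l$cache$dims_in
  gx <- from_clast(array(t(gxm), dim = c(d[1:3], d[5L], d[4L])))
  l$cache <- NULL
  gx
}

## ---- batch normalization (per channel over batch and space) ----

bn_layer <- function(C, momentum = 0.1, eps = 1e-5) {
  new_layer("bn",
            C = C, momentum = momentum, eps = eps,
            gamma = rep(1, C), beta = numeric(C),
            run_mean = numeric(C), run_var = rep(1, C),
            par_names = c("gamma", "beta"))
}

bn_fwd <- function(l, x, training) {
  d <- dim(x)
  xm <- as_channel_mat(x)
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    v <- colMeans(xc * xc)
    l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * mu
    l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * v
  } else {
    mu <- l$run_mean
    v <- l$run_var
    xc <- sweep(xm, 2L, mu)
  }
  inv_std <- 1 / sqrt(v + l$eps)
  xhat <- sweep(xc, 2L, inv_std, `*`)
  y <- sweep(sweep(xhat, 2L, l$gamma, `*`), 2L, l$beta, `+`)
  if (training) l$cache <- list(xhat = xhat, inv_std = inv_std, d = d)
  from_channel_mat(y, d)
}

bn_bwd <- function(l, gy) {
  d <- l$cache$d
  gm <- as_channel_mat(gy)
  xhat <- l$cache$xhat
  n <- nrow(gm)
  l$ggamma <- l$ggamma + colSums(gm * xhat)
  l$gbeta <- l$gbeta + colSums(gm)
  dxhat <- sweep(gm, 2L, l$gamma, `*`)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  gx <- sweep(dxhat, 2L, s1 / n) - sweep(xhat, 2L, s2 / n, `*`)
  gx <- sweep(gx, 2L, l$cache$inv_std, `*`)
  l$cache <- NULL
  from_channel_mat(gx, d)
}

## ---- pointwise layers ----

relu_fwd <- function(l, x, training = TRUE) {
  y <- pmax(x, 0)
  if (training) l$cache <- x > 0
  y
}
relu_bwd <- function(l, gy) {
  gx <- gy * l$cache
  l$cache <- NULL
  gx
}

dropout_layer <- function(p) new_layer("dropout", p = p)
dropout_fwd <- function(l, x, training) {
  if (!training || l$p <= 0) return(x)
  mask <- array((runif(length(x)) >= l$p) / (1 - l$p), dim = dim(x))
  l$cache <- mask
  x * mask
}
dropout_bwd <- function(l, gy) {
  if (is.null(l$cache)) return(gy)
  gx <- gy * l$cache
  l$cache <- NULL
  gx
}

## ---- 2x2x2 max pooling, stride 2 ----

pool_layer <- function() new_layer("pool")
pool_fwd <- function(l, x, training = TRUE) {
  r <- .maxpool3d_fwd(x, as.integer(dim(x)))
  if (training) l$cache <- list(idx = r$idx, dims_in = as.integer(dim(x)))
  r$y
}
pool_bwd <- function(l, gy) {
  gx <- .maxpool3d_bwd(gy, l$cache$idx, l$cache$dims_in)
  l$cache <- NULL
  gx
}

## ---- channel concatenation ----

cat_channels <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1L]])
  chans <- vapply(xs, function(x) dim(x)[4L], integer(1))
  out <- array(unlist(lapply(xs, to_clast), use.names = FALSE),
               dim = c(d[1:3], d[5L], sum(chans)))
  from_clast(out)
}

split_channels <- function(g, chans) {
  gcl <- to_clast(g)
  d <- dim(gcl)
  off <- 0L
  out <- vector("list", length(chans))
  for (i in seq_along(chans)) {
    out[[i]] <- from_clast(gcl[, , , , off + seq_len(chans[i]), drop = FALSE])
    off <- off + chans[i]
  }
  out
}

## ---- parameter plumbing ----

layer_trainable <- function(l) !is.null(l$par_names)

zero_layer_grads <- function(l) {
  if (!layer_trainable(l)) return(invisible(NULL))
  for (p in l$par_names) {
    g <- paste0("g", p)
    assign(g, get(p, envir = l) * 0, envir = l)
  }
  invisible(NULL)
}
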