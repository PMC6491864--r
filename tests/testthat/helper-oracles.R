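# Independent oracles the implementation is tested against. These are kept
# deliberately naive (literal loops over the defining sums) and share no
# code with the package internals.

# Literal evaluation of the dilated-convolution sum out(p) = sum_t F(p - l t) h(t)
# over every valid output position, with a quadruple loop.
brute_dilated_conv <- function(sig, ker, rate) {
  r <- (dim(ker)[1] - 1L) %/% 2L
  n <- dim(sig)
  od <- n - 2L * rate * r
  out <- array(NA_real_, od)
  for (pz in seq_len(od[3])) for (py in seq_len(od[2])) for (px in seq_len(od[1])) {
    p <- c(px, py, pz) + rate * r
    acc <- 0
    for (tz in -r:r) for (ty in -r:r) for (tx in -r:r) {
      s <- p - rate * c(tx, ty, tz)
      acc <- acc + sig[s[1], s[2], s[3]] * ker[tx + r + 1, ty + r + 1, tz + r + 1]
    }
    out[px, py, pz] <- acc
  }
  out
}

# Receptive-field side measured by input perturbation: push a delta through
# a stack of positive-weight stride-1 dilated convolutions and measure the
# support of the output change along one axis.
perturbation_rf_side <- function(kernels_rates, size) {
  x0 <- array(0, c(size, size, size, 1L, 1L))
  x1 <- x0
  ctr <- (size + 1L) %/% 2L
  x1[ctr, ctr, ctr, 1L, 1L] <- 1
  layers <- lapply(kernels_rates, function(kr) {
    l <- ddunet:::conv_layer(1L, 1L, k = kr[1], rate = kr[2])
    l$W <- abs(l$W) + 0.01  # positive weights: no accidental cancellation
    l$b <- 0
    l
  })
  fwd <- function(x) {
    for (l in layers) x <- ddunet:::conv_fwd(l, x, training = FALSE)
    x
  }
  dimsupp <- abs(fwd(x1) - fwd(x0)) > 1e-12
  idx <- which(dimsupp, arr.ind = TRUE)
  max(idx[, 1]) - min(idx[, 1]) + 1L
}

# O(|dA| * |dB|) double loop over boundary voxels, pure R.
brute_assd <- function(a, b, class, spacing = c(1, 1, 1)) {
  bnd <- function(mask) {
    d <- dim(mask)
    out <- NULL
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (!mask[i, j, k]) next
      nb <- c(
        if (i > 1) mask[i - 1, j, k] else FALSE,
        if (i < d[1]) mask[i + 1, j, k] else FALSE,
        if (j > 1) mask[i, j - 1, k] else FALSE,
        if (j < d[2]) mask[i, j + 1, k] else FALSE,
        if (k > 1) mask[i, j, k - 1] else FALSE,
        if (k < d[3]) mask[i, j, k + 1] else FALSE)
      if (!all(nb)) out <- rbind(out, c(i, j, k))
    }
    out
  }
  ba <- bnd(a == class)
  bb <- bnd(b == class)
  if (is.null(ba) || is.null(bb)) return(NA_real_)
  one_way <- function(p, q) {
    mean(apply(p, 1, function(e) {
      sqrt(min(colSums((t(q) - e)^2 * spacing^2)))
    }))
  }
  (one_way(ba, bb) + one_way(bb, ba)) / 2
}

# Shared tiny network spec for fast structural tests.
tiny_spec <- function(variant = "resdunet", K = 3L, dropout = 0) {
  network_spec(variant, in_channels = 2L, num_classes = K,
               base_channels = 2L, dense_layers = 2L,
               dilation_schedule = c(1L, 2L), dropout_rate = dropout)
}
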