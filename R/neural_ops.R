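#' Dilated convolution of a 3D signal (reference semantics)
#'
#' Computes the l-dilated convolution of a real-valued signal `F` on a finite
#' box of the integer lattice with a cubic filter `h` supported on
#' `[-r, r]^3`: the output at position `p` is `sum_{s + l t = p} F(s) h(t)`,
#' i.e. `sum_t F(p - l t) h(t)`. With `rate = 1` this is the ordinary
#' (flipped-kernel) convolution. This function is a correctness reference:
#' the network layers use an optimized im2col backend that is tested against
#' it (the backend follows the cross-correlation convention, so comparisons
#' mirror the kernel).
#'
#' @param signal 3D numeric array, the signal `F` (finite support, all
#'   entries finite).
#' @param kernel 3D numeric array with odd side `2r + 1`, indexed over
#'   `[-r, r]^3` (element `[1,1,1]` is `t = (-r,-r,-r)`).
#' @param rate positive integer dilation rate `l`.
#' @param pad if `TRUE`, zero-pad so the output has the same dimensions as
#'   the input; if `FALSE` (default) return only the fully valid region,
#'   of dimension `dim(signal) - 2 * rate * r` per axis.
#' @return 3D numeric array.
#' @export
dilated_conv3d <- function(signal, kernel, rate = 1L, pad = FALSE) {
  if (length(rate) != 1L || !is.finite(rate) || rate < 1 || rate != round(rate))
    stop("'rate' must be a positive integer")
  rate <- as.integer(rate)
  if (length(dim(signal)) != 3L) stop("'signal' must be a 3D array")
  kd <- dim(kernel)
  if (length(kd) != 3L || length(unique(kd)) != 1L || kd[1] %% 2L == 0L)
    stop("'kernel' must be a cubic array with odd side")
  if (!all(is.finite(signal)) || !all(is.finite(kernel)))
    stop("signal and kernel must be finite")
  r <- (kd[1] - 1L) %/% 2L
  n <- dim(signal)
  if (pad) {
    padded <- array(0, n + 2L * rate * r)
    padded[rate * r + seq_len(n[1]), rate * r + seq_len(n[2]),
           rate * r + seq_len(n[3])] <- signal
    signal <- padded
    n <- dim(signal)
  }
  out_dim <- n - 2L * rate * r
  if (any(out_dim < 1L))
    stop("signal support too small for this kernel and rate; use pad = TRUE")
  out <- array(0, out_dim)
  # out(p) = sum_t F(p - l t) h(t); p runs over the valid box.
  for (tz in -r:r) for (ty in -r:r) for (tx in -r:r) {
    w <- kernel[tx + r + 1L, ty + r + 1L, tz + r + 1L]
    if (w == 0) next
    # 1-based: valid p has offset rate*r; source index p - rate * t
    ix <- (rate * r - rate * tx) + seq_len(out_dim[1])
    iy <- (rate * r - rate * ty) + seq_len(out_dim[2])
    iz <- (rate * r - rate * tz) + seq_len(out_dim[3])
    out <- out + w * signal[ix, iy, iz]
  }
  out
}

#' Receptive-field arithmetic for a stack of convolutional layers
#'
#' For a sequential stack of cubic convolutions described by
#' `(kernel size, dilation rate, stride)` triples, computes the side length
#' (in input voxels) of the cubic receptive field of one output unit after
#' each layer, together with the cumulative stride. For a stride-1 stack the
#' closed form is `side = 1 + sum_i rate_i * (k_i - 1)`: dilation enlarges
#' the receptive field without any loss of spatial resolution.
#'
#' @param layers a data.frame (or list of numeric triples) with columns/
#'   elements `kernel`, `rate`, `stride`.
#' @return a data.frame with one row per layer: `kernel`, `rate`, `stride`,
#'   `rf_side` (cumulative receptive-field side in input voxels) and
#'   `cum_stride`.
#' @export
receptive_field <- function(layers) {
  if (is.data.frame(layers)) {
    tab <- layers
  } else if (is.list(layers) && length(layers)) {
    tab <- as.data.frame(do.call(rbind, lapply(layers, function(x) {
      x <- as.numeric(x)
      if (length(x) == 2L) x <- c(x, 1)
      x
    })))
    names(tab) <- c("kernel", "rate", "stride")
  } else {
    stop("'layers' must be a non-empty layer list")
  }
  if (nrow(tab) == 0L) stop("'layers' must be a non-empty layer list")
  if (any(tab$kernel < 1) || any(tab$rate < 1) || any(tab$stride < 1))
    stop("kernel, rate and stride must all be >= 1")
  side <- 1
  jump <- 1
  rf <- numeric(nrow(tab))
  cum <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    side <- side + jump * tab$rate[i] * (tab$kernel[i] - 1)
    jump <- jump * tab$stride[i]
    rf[i] <- side
    cum[i] <- jump
  }
  tab$rf_side <- rf
  tab$cum_stride <- cum
  tab
}
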