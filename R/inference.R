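# Overlapped sliding-window prediction. Each window is forwarded in eval
# mode, its per-voxel argmax labels cast one vote each, and the final label
# of a voxel is the vote plurality (ties to the smallest class index, so
# background wins any tie it is part of).

#' Sliding-window origins covering a volume
#'
#' Regular stride lattice per axis, plus an end-aligned window whenever
#' `dim - patch` is not a stride multiple, so that every voxel is covered
#' at least once.
#'
#' @param dims integer length-3 volume dimensions.
#' @param patch_size cubic window side.
#' @param stride window stride (default 8, the published setting for
#'   24-voxel patches).
#' @return integer matrix (n x 3) of 1-based window origins.
#' @export
window_origins <- function(dims, patch_size, stride = 8L) {
  dims <- as.integer(dims)
  R <- as.integer(patch_size)
  if (any(R > dims)) stop("patch_size exceeds the volume dimensions")
  ax <- lapply(dims, function(n) {
    o <- seq.int(1L, n - R + 1L, as.integer(stride))
    if (o[length(o)] != n - R + 1L) o <- c(o, n - R + 1L)
    o
  })
  g <- as.matrix(expand.grid(x = ax[[1L]], y = ax[[2L]], z = ax[[3L]],
                             KEEP.OUT.ATTRS = FALSE))
  storage.mode(g) <- "integer"
  g
}

#' Predict a full volume by majority vote over sliding windows
#'
#' @param net a trained `ddu_network`.
#' @param image 4D (x, y, z, channel) array; channels must match the
#'   network's `in_channels`.
#' @param patch_size window side (divisible by 8).
#' @param stride window stride.
#' @param batch_windows windows forwarded together per pass (throughput
#'   only; the result is independent of this grouping).
#' @return list: `labels`, the 3D integer label volume in `0..K-1`, and
#'   `votes`, the (x, y, z, K) integer vote-count grid (per voxel, votes
#'   sum to the number of windows covering it).
#' @export
predict_volume <- function(net, image, patch_size = 24L, stride = 8L,
                           batch_windows = 4L) {
  d <- dim(image)
  if (length(d) != 4L || d[4L] != net$spec$in_channels)
    stop("image must be (x, y, z, channel) with channels matching the network")
  K <- net$spec$num_classes
  org <- window_origins(d[1:3], patch_size, stride)
  votes <- array(0L, c(d[1:3], K))
  R <- as.integer(patch_size)
  for (start in seq.int(1L, nrow(org), batch_windows)) {
    rows <- start:min(start + batch_windows - 1L, nrow(org))
    x <- array(0, c(R, R, R, d[4L], length(rows)))
    for (j in seq_along(rows)) {
      o <- org[rows[j], ]
      x[, , , , j] <- image[o[1L]:(o[1L] + R - 1L), o[2L]:(o[2L] + R - 1L),
                            o[3L]:(o[3L] + R - 1L), , drop = FALSE]
    }
    scores <- network_forward(net, x, training = FALSE)
    for (j in seq_along(rows)) {
      o <- org[rows[j], ]
      lab <- argmax_label(array(scores[, , , , j], c(R, R, R, K)),
                          normalized = FALSE)
      win_votes <- votes[o[1L]:(o[1L] + R - 1L), o[2L]:(o[2L] + R - 1L),
                         o[3L]:(o[3L] + R - 1L), , drop = FALSE]
      oh <- array(0L, c(R, R, R, K))
      oh[cbind(which(lab >= 0L, arr.ind = TRUE), as.integer(lab) + 1L)] <- 1L
      votes[o[1L]:(o[1L] + R - 1L), o[2L]:(o[2L] + R - 1L),
            o[3L]:(o[3L] + R - 1L), ] <- win_votes + oh
    }
  }
  vm <- matrix(votes, ncol = K)
  labels <- array(max.col(vm, ties.method = "first") - 1L, d[1:3])
  list(labels = labels, votes = votes)
}

#' Per-voxel argmax labeling of a probability (or score) map
#'
#' @param prob 4D (x, y, z, K) array; per-voxel class probabilities (or any
#'   monotone scores). Ties go to the smallest class index.
#' @param normalized require each voxel's vector to be a probability
#'   simplex point (nonnegative, sums to 1) to within 1e-6.
#' @return 3D integer label array in `0..K-1`.
#' @export
argmax_label <- function(prob, normalized = TRUE) {
  d <- dim(prob)
  if (length(d) != 4L) stop("'prob' must be a 4D (x, y, z, K) array")
  m <- matrix(prob, ncol = d[4L])
  if (anyNA(m) || any(!is.finite(m))) stop("probabilities contain NaN/Inf")
  if (normalized &&
      (any(m < -1e-6) || any(abs(rowSums(m) - 1) > 1e-6)))
    stop("'prob' is not voxel-wise normalized; use normalized = FALSE for scores")
  array(max.col(m, ties.method = "first") - 1L, d[1:3])
}
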