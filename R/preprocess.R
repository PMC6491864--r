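# Localization and intensity preprocessing: a hippocampus bounding box with
# a 32-voxel safety margin computed over the training labels, cropping,
# monotone histogram matching to a reference subject, and left-right flip
# augmentation that doubles the training set.

#' Bounding box of the labeled foreground, with margin
#'
#' Scans one or more label volumes for the minimum and maximum x, y, z
#' positions of any nonzero voxel, enlarges the box by `margin` voxels in
#' each direction, and clamps it to the image extent. At prediction time
#' the box computed from the training subjects is applied unchanged (it is
#' assumed large enough to cover unseen subjects).
#'
#' @param labels a 3D integer label array, or a list of them on the same
#'   grid.
#' @param margin voxels added on every side (default 32).
#' @return an object of class `bounding_box`: a 2 x 3 matrix of 1-based
#'   inclusive `min` / `max` voxel indices, with the native grid dimension
#'   attached.
#' @export
compute_bounding_box <- function(labels, margin = 32L) {
  if (!is.list(labels)) labels <- list(labels)
  ext <- dim(labels[[1L]])
  lo <- rep(Inf, 3)
  hi <- rep(-Inf, 3)
  for (lv in labels) {
    if (!identical(dim(lv), ext)) stop("all label volumes must share one grid")
    nz <- which(lv != 0, arr.ind = TRUE)
    if (nrow(nz)) {
      lo <- pmin(lo, apply(nz, 2L, min))
      hi <- pmax(hi, apply(nz, 2L, max))
    }
  }
  if (!all(is.finite(lo)))
    stop("no foreground voxel found in any label volume")
  box <- rbind(min = pmax(lo - margin, 1L), max = pmin(hi + margin, ext))
  storage.mode(box) <- "integer"
  colnames(box) <- c("x", "y", "z")
  structure(box, extent = as.integer(ext), class = "bounding_box")
}

#' Crop a volume to a bounding box
#'
#' Works on 3D label/image arrays and on 4D (x, y, z, channel) arrays. The
#' native grid size and box offset are carried by the box itself, so
#' [uncrop()] can place a prediction back on the native grid.
#'
#' @param volume 3D or 4D array.
#' @param box a [compute_bounding_box()] result.
#' @return the cropped array.
#' @export
crop <- function(volume, box) {
  d <- dim(volume)
  if (any(box["max", ] > d[1:3]) || any(box["min", ] < 1L))
    stop("bounding box exceeds the volume extent")
  ix <- box["min", 1L]:box["max", 1L]
  iy <- box["min", 2L]:box["max", 2L]
  iz <- box["min", 3L]:box["max", 3L]
  if (length(d) == 3L) volume[ix, iy, iz, drop = FALSE]
  else volume[ix, iy, iz, , drop = FALSE]
}

#' @rdname crop
#' @param background fill value outside the box (default 0).
#' @return `uncrop()` returns the volume embedded in the native grid, with
#'   `background` outside the box.
#' @export
uncrop <- function(volume, box, background = 0) {
  ext <- attr(box, "extent")
  d <- dim(volume)
  out_dim <- if (length(d) == 3L) ext else c(ext, d[4L])
  out <- array(background, out_dim)
  ix <- box["min", 1L]:box["max", 1L]
  iy <- box["min", 2L]:box["max", 2L]
  iz <- box["min", 3L]:box["max", 3L]
  if (length(d) == 3L) out[ix, iy, iz] <- volume
  else out[ix, iy, iz, ] <- volume
  if (is.integer(volume)) storage.mode(out) <- "integer"
  out
}

#' Histogram matching by monotone quantile mapping
#'
#' Remaps the intensities of `moving` so its empirical quantile function
#' approximates that of `reference`, using `n_quantiles` evenly spaced
#' quantile knots and linear interpolation between them. The mapping is
#' monotone, so the rank order of voxels is preserved.
#'
#' @param moving,reference numeric arrays (any shape).
#' @param n_quantiles number of quantile knots (default 256).
#' @return array shaped like `moving` with matched intensities.
#' @export
histogram_match <- function(moving, reference, n_quantiles = 256L) {
  if (length(unique(range(moving))) == 1L) {
    warning("constant moving image; shifting to the reference median")
    return(array(stats::median(reference), dim = dim(moving)))
  }
  probs <- seq(0, 1, length.out = n_quantiles)
  qm <- quantile(moving, probs, names = FALSE, type = 7)
  qr <- quantile(reference, probs, names = FALSE, type = 7)
  # collapse duplicated knots so approx() sees a function
  keep <- !duplicated(qm)
  out <- approx(qm[keep], qr[keep], xout = as.numeric(moving),
                rule = 2, ties = "ordered")$y
  array(out, dim = dim(moving))
}

#' Left-right flip of an image/label pair
#'
#' Mirrors both the image (3D, or 4D with trailing channel dim) and the
#' label volume along the left-right axis. Subfield class IDs are
#' side-agnostic (one ID covers the left and right instance), so labels are
#' not renumbered.
#'
#' @param image 3D or 4D numeric array.
#' @param labels 3D integer array.
#' @param axis the left-right axis (1, 2 or 3). If `NULL` a warning is
#'   emitted and axis 1 is used; pipelines reading NIfTI should derive the
#'   axis from the volume orientation.
#' @return list with mirrored `image` and `labels`.
#' @export
flip_lr <- function(image, labels, axis = NULL) {
  if (is.null(axis)) {
    warning("no orientation metadata; assuming the left-right axis is axis 1")
    axis <- 1L
  }
  list(image = flip_axis(image, axis), labels = flip_axis(labels, axis))
}

flip_axis <- function(x, axis) {
  idx <- rep(list(quote(expr = )), length(dim(x)))
  idx[[axis]] <- rev(seq_len(dim(x)[axis]))
  do.call(`[`, c(list(x), idx, drop = FALSE))
}
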