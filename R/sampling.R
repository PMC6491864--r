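# Training-patch extraction: every stride-2 window that contains at least
# one hippocampal (nonzero-label) voxel is a candidate; candidates are
# numbered in raster order, randomly reordered, and the first half kept.

#' Enumerate candidate patch origins
#'
#' Lists, in raster order (first axis fastest), every origin on the stride
#' lattice whose `patch_size`^3 window contains at least one nonzero label
#' voxel. A summed-volume table makes the foreground test O(1) per window.
#'
#' @param labels 3D integer label array (cropped grid).
#' @param patch_size cubic window side R in voxels.
#' @param stride lattice stride (default 2, applied per axis).
#' @return integer matrix (n x 3) of 1-based window origins.
#' @export
enumerate_candidate_patches <- function(labels, patch_size, stride = 2L) {
  d <- dim(labels)
  R <- as.integer(patch_size)
  if (any(R > d)) stop("patch_size exceeds the volume dimensions")
  fg <- array(as.numeric(labels != 0), d)
  # summed-volume table with a zero border
  sat <- array(0, d + 1L)
  sat[-1L, -1L, -1L] <- fg
  sat <- apply(apply(apply(sat, c(2L, 3L), cumsum), c(1L, 3L), cumsum),
               c(1L, 2L), cumsum)
  sat <- aperm(sat, c(3L, 2L, 1L))  # undo apply()'s dimension rotation
  ox <- seq.int(1L, d[1L] - R + 1L, stride)
  oy <- seq.int(1L, d[2L] - R + 1L, stride)
  oz <- seq.int(1L, d[3L] - R + 1L, stride)
  cnt <- sat[ox + R, oy + R, oz + R, drop = FALSE] -
    sat[ox, oy + R, oz + R, drop = FALSE] -
    sat[ox + R, oy, oz + R, drop = FALSE] -
    sat[ox + R, oy + R, oz, drop = FALSE] +
    sat[ox, oy, oz + R, drop = FALSE] +
    sat[ox, oy + R, oz, drop = FALSE] +
    sat[ox + R, oy, oz, drop = FALSE] -
    sat[ox, oy, oz, drop = FALSE]
  hit <- which(cnt > 0.5)  # raster order: x fastest, then y, then z
  if (!length(hit))
    return(matrix(integer(0), ncol = 3L,
                  dimnames = list(NULL, c("x", "y", "z"))))
  ar <- arrayInd(hit, dim(cnt))
  out <- cbind(x = ox[ar[, 1L]], y = oy[ar[, 2L]], z = oz[ar[, 3L]])
  storage.mode(out) <- "integer"
  out
}

#' Select training patches: random reorder, keep the first half
#'
#' The candidate numbers are randomly permuted and the first
#' `floor(n / 2)` retained. Patches themselves are materialized lazily from
#' the referenced volumes ([extract_patch()]), so a patch set stores only
#' origins and the seed.
#'
#' @param image 4D (x, y, z, channel) array: the concatenated modalities.
#' @param labels 3D integer label array on the same grid.
#' @param candidates origin matrix from [enumerate_candidate_patches()].
#' @param patch_size cubic patch side R.
#' @param seed RNG seed for the permutation (one per subject).
#' @return an object of class `patch_set`.
#' @export
select_training_patches <- function(image, labels, candidates, patch_size,
                                    seed = 1L) {
  if (nrow(candidates) == 0L) stop("empty candidate list")
  set.seed(seed)
  ord <- sample.int(nrow(candidates))
  keep <- ord[seq_len(nrow(candidates) %/% 2L)]
  structure(list(image = image, labels = labels,
                 origins = candidates[keep, , drop = FALSE],
                 patch_size = as.integer(patch_size),
                 seed = as.integer(seed)),
            class = "patch_set")
}

#' Materialize one patch of a patch set
#' @param ps a `patch_set`.
#' @param i patch index.
#' @return list with `image` (R,R,R,C) and `labels` (R,R,R) sub-arrays.
#' @export
extract_patch <- function(ps, i) {
  o <- ps$origins[i, ]
  R <- ps$patch_size
  ix <- o[1L]:(o[1L] + R - 1L)
  iy <- o[2L]:(o[2L] + R - 1L)
  iz <- o[3L]:(o[3L] + R - 1L)
  list(image = ps$image[ix, iy, iz, , drop = FALSE],
       labels = ps$labels[ix, iy, iz, drop = FALSE])
}
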