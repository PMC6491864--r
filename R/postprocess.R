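# Connected-component false-positive removal. Patch-trained networks only
# see local context, so look-alike structures far from the hippocampi (e.g.
# caudate) can appear as isolated labeled islands; keeping the two largest
# connected regions (left + right hippocampus) removes them.

#' Connected components of the labeled foreground
#'
#' Components of the binarized mask (any nonzero class) under 6 or 26
#' connectivity. Component IDs are assigned in order of each component's
#' smallest linear voxel index.
#'
#' @param labels 3D integer label array.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners; default).
#' @return list: `labels_cc`, the 3D integer component-ID array (0 =
#'   background), and `table`, a data.frame with one row per component:
#'   `id`, `n_voxels`, bounding-box columns (`xmin`..`zmax`), `classes`
#'   (comma-separated label values present) and `first_index`.
#' @export
connected_components <- function(labels, connectivity = 26L) {
  cc <- .label_components3d(labels != 0, as.integer(dim(labels)),
                            as.integer(connectivity))
  n <- max(cc)
  if (n == 0L)
    return(list(labels_cc = cc,
                table = data.frame(id = integer(0), n_voxels = integer(0),
                                   xmin = integer(0), xmax = integer(0),
                                   ymin = integer(0), ymax = integer(0),
                                   zmin = integer(0), zmax = integer(0),
                                   classes = character(0),
                                   first_index = integer(0))))
  rows <- lapply(seq_len(n), function(id) {
    idx <- which(cc == id)
    ar <- arrayInd(idx, dim(labels))
    data.frame(id = id, n_voxels = length(idx),
               xmin = min(ar[, 1L]), xmax = max(ar[, 1L]),
               ymin = min(ar[, 2L]), ymax = max(ar[, 2L]),
               zmin = min(ar[, 3L]), zmax = max(ar[, 3L]),
               classes = paste(sort(unique(labels[idx])), collapse = ","),
               first_index = idx[1L])
  })
  list(labels_cc = cc, table = do.call(rbind, rows))
}

#' Keep only the largest connected regions
#'
#' Foreground outside the `n_keep` largest components is reset to
#' background; subfield classes inside the kept components are unchanged.
#' A size tie for the last kept place is broken deterministically in favor
#' of the component with the smaller minimum linear voxel index.
#'
#' @param labels 3D integer label array.
#' @param n_keep number of components to keep (default 2: left + right
#'   hippocampus).
#' @param connectivity 6 or 26 (default).
#' @return filtered 3D integer label array.
#' @export
keep_largest_components <- function(labels, n_keep = 2L, connectivity = 26L) {
  cc <- connected_components(labels, connectivity)
  tab <- cc$table
  if (nrow(tab) <= n_keep) return(labels)
  keep <- tab$id[order(-tab$n_voxels, tab$first_index)][seq_len(n_keep)]
  out <- labels
  out[!(cc$labels_cc %in% keep)] <- 0L
  storage.mode(out) <- "integer"
  out
}
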