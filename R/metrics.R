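# Segmentation evaluation: Dice overlap and average symmetric surface
# distance (ASSD), per subfield class and class-averaged. Boundaries are
# foreground voxels with at least one background 6-neighbor (voxels outside
# the grid count as background); distances are Euclidean between voxel
# centers in physical units (index times spacing).

#' Dice coefficient for one class
#'
#' `Dice = 2 V(A intersect B) / (V(A) + V(B))` on the binarized masks of
#' class `class` in the manual (`a`) and automated (`b`) segmentations.
#'
#' @param a,b 3D integer label arrays on the same grid.
#' @param class the class value to evaluate.
#' @return Dice in `[0, 1]`, or `NA` when the class is absent from both
#'   volumes (undefined; excluded from averages).
#' @export
dice <- function(a, b, class) {
  stopifnot(identical(dim(a), dim(b)))
  ma <- a == class
  mb <- b == class
  denom <- sum(ma) + sum(mb)
  if (denom == 0L) return(NA_real_)
  2 * sum(ma & mb) / denom
}

#' Average symmetric surface distance for one class
#'
#' `(mean_{e in dA} min_{f in dB} d(e, f) + mean_{e in dB} min_{f in dA}
#' d(e, f)) / 2`, with `d` the Euclidean distance between voxel centers in
#' physical units.
#'
#' @param a,b 3D integer label arrays on the same grid.
#' @param class the class value to evaluate.
#' @param spacing voxel spacing, length 3 (mm per voxel; default 1 mm
#'   isotropic, i.e. voxel units).
#' @return nonnegative distance (same units as `spacing`), or `NA` when
#'   the class is empty in either volume (the distance is undefined).
#' @export
assd <- function(a, b, class, spacing = c(1, 1, 1)) {
  stopifnot(identical(dim(a), dim(b)), length(spacing) == 3L)
  ba <- boundary_voxels(a == class)
  bb <- boundary_voxels(b == class)
  if (nrow(ba) == 0L || nrow(bb) == 0L) return(NA_real_)
  dab <- .min_surface_dists(ba, bb, as.numeric(spacing))
  dba <- .min_surface_dists(bb, ba, as.numeric(spacing))
  (mean(dab) + mean(dba)) / 2
}

# 0-based (i, j, k) coordinates of mask voxels with >= 1 background
# 6-neighbor; the outside of the grid counts as background.
boundary_voxels <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[1L + seq_len(d[1L]), 1L + seq_len(d[2L]), 1L + seq_len(d[3L])] <- mask
  core <- function(dx, dy, dz)
    pad[1L + dx + seq_len(d[1L]), 1L + dy + seq_len(d[2L]),
        1L + dz + seq_len(d[3L])]
  interior <- core(-1L, 0L, 0L) & core(1L, 0L, 0L) &
    core(0L, -1L, 0L) & core(0L, 1L, 0L) &
    core(0L, 0L, -1L) & core(0L, 0L, 1L)
  idx <- which(mask & !interior, arr.ind = TRUE)
  storage.mode(idx) <- "integer"
  idx - 1L
}

#' Evaluate a predicted segmentation against ground truth
#'
#' Per-class Dice and ASSD for every foreground class, plus the unweighted
#' class average (classes undefined in both metrics' sense are excluded
#' from the average and flagged `missing`).
#'
#' @param pred,truth 3D integer label arrays on the same grid.
#' @param spacing voxel spacing (length 3).
#' @param class_names optional named map, e.g.
#'   `c("1" = "CA1", "2" = "CA2/3")`; defaults to the class value.
#' @return data.frame (one row per class plus an `Average` row) with
#'   columns `class`, `name`, `dice`, `assd`, `missing`.
#' @export
evaluate_segmentation <- function(pred, truth, spacing = c(1, 1, 1),
                                  class_names = NULL) {
  if (!identical(dim(pred), dim(truth)))
    stop("prediction and truth grids do not match")
  classes <- sort(unique(c(truth[truth != 0], pred[pred != 0])))
  if (!length(classes)) stop("no foreground class in either volume")
  rows <- lapply(classes, function(k) {
    dc <- dice(truth, pred, k)
    ad <- assd(truth, pred, k, spacing)
    nm <- if (!is.null(class_names) && as.character(k) %in% names(class_names))
      class_names[[as.character(k)]] else as.character(k)
    data.frame(class = k, name = nm, dice = dc, assd = ad,
               missing = is.na(dc) && is.na(ad))
  })
  tab <- do.call(rbind, rows)
  avg <- data.frame(class = NA_integer_, name = "Average",
                    dice = mean(tab$dice, na.rm = TRUE),
                    assd = mean(tab$assd, na.rm = TRUE),
                    missing = FALSE)
  rbind(tab, avg)
}

#' Aggregate per-subject metric reports
#'
#' @param reports list of [evaluate_segmentation()] data.frames (one per
#'   subject).
#' @return data.frame with per-class and `Average` rows carrying the mean
#'   and standard deviation of Dice and ASSD over subjects.
#' @export
aggregate_reports <- function(reports) {
  all <- do.call(rbind, Map(function(r, i) transform(r, subject = i),
                            reports, seq_along(reports)))
  agg <- function(v, f) tapply(v, all$name, f, na.rm = TRUE)
  nm <- unique(all$name)
  data.frame(name = nm,
             dice_mean = as.numeric(agg(all$dice, mean)[nm]),
             dice_sd = as.numeric(agg(all$dice, sd)[nm]),
             assd_mean = as.numeric(agg(all$assd, mean)[nm]),
             assd_sd = as.numeric(agg(all$assd, sd)[nm]),
             row.names = NULL)
}
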