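# Deterministic two-modality phantoms with the geometry the pipeline
# assumes: a mirrored left/right pair of ellipsoidal "hippocampi", each
# partitioned into K-1 contiguous subfield compartments, plus small
# isolated distractor structures far from the target that share the
# hippocampal intensity profile but are labeled background -- these
# exercise the connected-component false-positive removal.

#' Phantom specification
#'
#' @param dims grid dimensions (x = left-right, y = the hippocampal long
#'   axis, z).
#' @param spacing voxel spacing in mm.
#' @param num_classes K, background included. The default 6 mirrors the
#'   five-subfield infant labeling (CA1, CA2/3, SUB, CA4/DG, Uncus); the
#'   `"adult"` preset of [generate_cohort()] uses 4 (CA1-3, SUB, CA4/DG).
#' @param center center of the left ellipsoid (the right one is mirrored
#'   across the mid-sagittal plane).
#' @param semi_axes ellipsoid semi-axes in voxels (x, y, z).
#' @param partition `"slab"`: K-1 equal bands along the long axis
#'   (anterior-most band emulating the uncus); `"shell"`: K-1 concentric
#'   bands of the ellipsoidal radius.
#' @param mean1,mean2 per-class mean intensities for modality 1 and 2,
#'   length K (background first). Modality 1 separates all classes;
#'   modality 2 is deliberately partially degenerate, so the value of a
#'   second modality can be probed.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param bias_amplitude amplitude of the smooth multiplicative quadratic
#'   bias field (fraction of signal).
#' @param n_distractors number of distractor islands.
#' @param distractor_radius min/max distractor radius (voxels).
#' @param distractor_min_dist minimum distance (voxels) from any distractor
#'   voxel to the hippocampal foreground.
#' @param seed RNG seed; the phantom is a pure function of the spec.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(52L, 44L, 36L), spacing = c(1, 1, 1),
                         num_classes = 6L,
                         center = c(14, 22, 18), semi_axes = c(6, 11, 5.5),
                         partition = c("slab", "shell"),
                         mean1 = NULL, mean2 = NULL,
                         noise_sd = 4, bias_amplitude = 0.1,
                         n_distractors = 2L, distractor_radius = c(2, 3),
                         distractor_min_dist = 10,
                         seed = 1L) {
  partition <- match.arg(partition)
  K <- as.integer(num_classes)
  if (K < 2L) stop("num_classes must be >= 2")
  if (is.null(mean1)) mean1 <- c(20, seq(50, 110, length.out = K - 1L))
  if (is.null(mean2)) {
    fg2 <- rep(c(90, 60, 75), length.out = K - 1L)
    mean2 <- c(25, fg2)
  }
  if (length(mean1) != K || length(mean2) != K)
    stop("intensity means must have one entry per class, background first")
  structure(list(dims = as.integer(dims), spacing = as.numeric(spacing),
                 num_classes = K, center = center, semi_axes = semi_axes,
                 partition = partition, mean1 = mean1, mean2 = mean2,
                 noise_sd = noise_sd, bias_amplitude = bias_amplitude,
                 n_distractors = as.integer(n_distractors),
                 distractor_radius = distractor_radius,
                 distractor_min_dist = distractor_min_dist,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one phantom subject
#'
#' @param spec a [phantom_spec()].
#' @return list: `image` (4D x,y,z,2 array: the two modalities), `labels`
#'   (3D integer, 0 = background), `distractor_mask` (3D logical), plus
#'   `spacing` and the `spec`. Fully determined by the spec (same seed,
#'   bitwise-identical output).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dims
  K <- spec$num_classes
  a <- spec$semi_axes
  cl <- spec$center
  cr <- c(d[1L] + 1 - cl[1L], cl[2L], cl[3L])
  for (cc in list(cl, cr))
    if (any(cc - a < 1) || any(cc + a > d))
      stop("infeasible geometry: ellipsoid exceeds the grid")
  set.seed(spec$seed)
  X <- array(rep(seq_len(d[1L]), times = d[2L] * d[3L]), d)
  Y <- array(rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]), d)
  Z <- array(rep(seq_len(d[3L]), each = d[1L] * d[2L]), d)
  labels <- array(0L, d)
  for (cc in list(cl, cr)) {
    rho2 <- ((X - cc[1L]) / a[1L])^2 + ((Y - cc[2L]) / a[2L])^2 +
      ((Z - cc[3L]) / a[3L])^2
    inside <- rho2 <= 1
    cls <- if (spec$partition == "slab") {
      t <- pmin(pmax((Y - (cc[2L] - a[2L])) / (2 * a[2L]), 0), 1 - 1e-9)
      as.integer(floor(t * (K - 1L)) + 1L)
    } else {
      t <- pmin(sqrt(rho2), 1 - 1e-9)
      as.integer(floor(t * (K - 1L)) + 1L)
    }
    labels[inside] <- cls[inside]
  }
  fg_idx <- which(labels != 0L, arr.ind = TRUE)
  # distractors: hippocampus-like intensity, background label, far away
  dist_mask <- array(FALSE, d)
  placed <- 0L
  tries <- 0L
  while (placed < spec$n_distractors && tries < 500L) {
    tries <- tries + 1L
    rad <- runif(1, spec$distractor_radius[1L], spec$distractor_radius[2L])
    ctr <- c(runif(1, 1 + rad, d[1L] - rad), runif(1, 1 + rad, d[2L] - rad),
             runif(1, 1 + rad, d[3L] - rad))
    gap <- sqrt(min((fg_idx[, 1L] - ctr[1L])^2 + (fg_idx[, 2L] - ctr[2L])^2 +
                      (fg_idx[, 3L] - ctr[3L])^2))
    if (gap < spec$distractor_min_dist + rad + 1) next
    sph <- (X - ctr[1L])^2 + (Y - ctr[2L])^2 + (Z - ctr[3L])^2 <= rad^2
    if (any(sph & dist_mask)) next
    dist_mask <- dist_mask | sph
    placed <- placed + 1L
  }
  if (placed < spec$n_distractors)
    stop("could not place all distractors at the required distance")
  # intensities: class means, distractors borrowing a mid-subfield profile
  dk <- max(2L, (K + 1L) %/% 2L)
  base1 <- spec$mean1[labels + 1L]
  base2 <- spec$mean2[labels + 1L]
  base1[dist_mask] <- spec$mean1[dk]
  base2[dist_mask] <- spec$mean2[dk]
  img <- array(0, c(d, 2L))
  for (mod in 1:2) {
    base <- array(if (mod == 1L) base1 else base2, d)
    u <- (X - 1) / (d[1L] - 1) * 2 - 1
    v <- (Y - 1) / (d[2L] - 1) * 2 - 1
    w <- (Z - 1) / (d[3L] - 1) * 2 - 1
    cf <- runif(6, -1, 1)
    poly <- cf[1L] * u + cf[2L] * v + cf[3L] * w +
      cf[4L] * u * v + cf[5L] * v * w + cf[6L] * (u^2 - w^2)
    poly <- poly / max(abs(poly), 1e-9)
    field <- 1 + spec$bias_amplitude * poly
    img[, , , mod] <- base * field + rnorm(prod(d), sd = spec$noise_sd)
  }
  list(image = img, labels = labels, distractor_mask = dist_mask,
       spacing = spec$spacing, spec = spec)
}

#' Generate a cohort of phantom subjects with inter-subject variation
#'
#' Derives one seed per subject from `seed` and jitters the geometry
#' (center, semi-axes) and per-class intensity means within small bounds,
#' emulating inter-subject anatomical and acquisition variation.
#'
#' @param n_subjects number of subjects.
#' @param base_spec the shared [phantom_spec()] (defaults to
#'   `phantom_spec()`).
#' @param seed cohort seed.
#' @param preset `"infant"` (K = 6, the default spec) or `"adult"` (K = 4).
#' @return list of subjects; each has `id`, `seed` and the
#'   [generate_phantom()] fields.
#' @export
generate_cohort <- function(n_subjects, base_spec = NULL, seed = 1L,
                            preset = c("infant", "adult")) {
  preset <- match.arg(preset)
  if (is.null(base_spec))
    base_spec <- if (preset == "adult") phantom_spec(num_classes = 4L)
                 else phantom_spec()
  stopifnot(n_subjects >= 1)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    set.seed(sub_seeds[i])
    sp <- base_spec
    sp$center <- sp$center + c(runif(1, -1, 1), runif(1, -1.5, 1.5),
                               runif(1, -1, 1))
    sp$semi_axes <- sp$semi_axes * runif(3, 0.92, 1.08)
    sp$mean1 <- sp$mean1 + rnorm(length(sp$mean1), sd = 2)
    sp$mean2 <- sp$mean2 + rnorm(length(sp$mean2), sd = 2)
    sp$seed <- sub_seeds[i]
    ph <- generate_phantom(sp)
    ph$id <- sprintf("sub-%02d", i)
    ph$seed <- sub_seeds[i]
    ph
  })
}
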