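# End-to-end pipeline entry points used by the command-line interface:
# simulate a phantom cohort to NIfTI, train on labeled volumes (bounding
# box -> crop -> histogram match -> flip augment -> patch sampling ->
# Adam), predict with sliding windows + majority vote + component
# filtering, and evaluate Dice/ASSD reports.

#' Pipeline configuration presets
#'
#' `"paper"` encodes the published hyperparameters (patch 24, batch 5,
#' lr 1e-4 with gamma = 0.1 every 10,000 iterations, weight decay 5e-4,
#' momentum 0.9, 60,000 iterations, prediction stride 8, keep the 2 largest
#' components). `"smoke"` is a desk-scale preset (tiny network, patch 16,
#' 50 iterations) that runs the whole chain on one CPU in minutes.
#'
#' @param preset `"paper"` or `"smoke"`.
#' @return nested named list of settings.
#' @export
default_config <- function(preset = c("paper", "smoke")) {
  preset <- match.arg(preset)
  cfg <- list(
    seed = 1L,
    model = list(variant = "resdunet", base_channels = 32L,
                 dense_layers = 3L, dilation_schedule = c(1L, 2L, 4L),
                 dropout_rate = 0.5, in_channels = 2L),
    data = list(margin = 32L, n_quantiles = 11L, flip_augment = TRUE,
                patch_size = 24L, sample_stride = 2L),
    train = list(batch_size = 5L, base_lr = 1e-4, gamma = 0.1,
                 step_size = 10000L, weight_decay = 5e-4, momentum = 0.9,
                 max_iterations = 60000L, metric_every = 1000L),
    inference = list(patch_size = 24L, stride = 8L, batch_windows = 4L),
    postprocess = list(enabled = TRUE, n_keep = 2L, connectivity = 26L))
  if (preset == "smoke") {
    cfg$model$base_channels <- 4L
    cfg$data$patch_size <- 16L
    cfg$train$batch_size <- 2L
    cfg$train$base_lr <- 1e-3
    cfg$train$max_iterations <- 50L
    cfg$train$metric_every <- 25L
    cfg$inference$patch_size <- 16L
  }
  cfg
}

#' Subfield class-name maps
#' @param preset `"infant"` (5 subfields) or `"adult"` (3 subfields).
#' @return named character vector keyed by class value.
#' @export
subfield_names <- function(preset = c("infant", "adult")) {
  preset <- match.arg(preset)
  if (preset == "infant")
    c("1" = "CA1", "2" = "CA2/3", "3" = "SUB", "4" = "CA4/DG", "5" = "Uncus")
  else
    c("1" = "CA1-3", "2" = "SUB", "3" = "CA4/DG")
}

## ---- NIfTI I/O ----

write_volume <- function(x, path, spacing = c(1, 1, 1), template = NULL) {
  img <- if (is.null(template)) RNifti::asNifti(x, pixdim = spacing)
         else RNifti::asNifti(x, reference = template)
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  attr(arr, "spacing") <- RNifti::pixdim(img)
  attr(arr, "image") <- img
  arr
}

#' Simulate a phantom cohort to disk
#'
#' Writes, per subject, the two modality volumes and the label volume as
#' NIfTI, plus a JSON manifest (subject IDs, per-subject seeds, spec), the
#' fixture source for the rest of the pipeline.
#'
#' @param out_dir output directory (created if missing).
#' @param n_subjects cohort size.
#' @param seed cohort seed.
#' @param preset `"infant"` or `"adult"` labeling.
#' @return the manifest, invisibly.
#' @export
run_simulate <- function(out_dir, n_subjects = 10L, seed = 1L,
                         preset = c("infant", "adult")) {
  preset <- match.arg(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(n_subjects, seed = seed, preset = preset)
  subjects <- lapply(cohort, function(s) {
    base <- file.path(out_dir, s$id)
    write_volume(s$image[, , , 1L], paste0(base, "_mod1.nii.gz"), s$spacing)
    write_volume(s$image[, , , 2L], paste0(base, "_mod2.nii.gz"), s$spacing)
    lab <- s$labels
    storage.mode(lab) <- "integer"
    write_volume(lab, paste0(base, "_labels.nii.gz"), s$spacing)
    list(id = s$id, seed = s$seed,
         files = paste0(basename(base), c("_mod1.nii.gz", "_mod2.nii.gz",
                                          "_labels.nii.gz")))
  })
  manifest <- list(n_subjects = n_subjects, seed = seed, preset = preset,
                   num_classes = cohort[[1L]]$spec$num_classes,
                   spacing = cohort[[1L]]$spacing, subjects = subjects)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Load a simulated cohort from disk
#' @param dir directory written by [run_simulate()].
#' @return list of subjects with `id`, `image` (4D), `labels`, `spacing`.
#' @export
load_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  lapply(seq_len(manifest$n_subjects), function(i) {
    s <- manifest$subjects[i, ]
    files <- file.path(dir, unlist(s$files))
    m1 <- read_volume(files[1L])
    m2 <- read_volume(files[2L])
    lab <- read_volume(files[3L])
    img <- array(0, c(dim(m1), 2L))
    img[, , , 1L] <- m1
    img[, , , 2L] <- m2
    labels <- array(as.integer(round(lab)), dim(lab))
    list(id = s$id, image = img, labels = labels,
         spacing = as.numeric(manifest$spacing),
         num_classes = manifest$num_classes)
  })
}

#' Train a network on labeled subjects
#'
#' Full training path: foreground bounding box (with margin) over the
#' training labels, cropping, per-modality histogram matching to the first
#' training subject, optional left-right flip augmentation (doubling the
#' subject list), stride-2 foreground patch sampling keeping a random
#' half, and Adam optimization. The checkpoint stores the network, the
#' bounding box and the matching reference so prediction reproduces the
#' training-time preprocessing.
#'
#' @param subjects list of subjects (`image` 4D, `labels` 3D), e.g. from
#'   [load_cohort()] or [generate_cohort()].
#' @param out_dir run directory for the checkpoint, loss log and resolved
#'   config.
#' @param config a [default_config()]-style list.
#' @param train_ids indices of training subjects (default: all).
#' @param target_dice optional early-stop threshold on the training-Dice
#'   monitor.
#' @return list: `checkpoint` path, `log`, `box`, `iterations`.
#' @export
run_train <- function(subjects, out_dir, config = default_config("smoke"),
                      train_ids = seq_along(subjects), target_dice = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tr <- subjects[train_ids]
  K <- max(vapply(tr, function(s) max(s$labels), integer(1))) + 1L
  box <- compute_bounding_box(lapply(tr, `[[`, "labels"),
                              margin = config$data$margin)
  tr <- lapply(tr, function(s) {
    s$image <- crop(s$image, box)
    s$labels <- crop(s$labels, box)
    s
  })
  ref <- tr[[1L]]$image
  for (i in seq_along(tr)) for (m in 1:2)
    tr[[i]]$image[, , , m] <- histogram_match(tr[[i]]$image[, , , m],
                                              ref[, , , m],
                                              config$data$n_quantiles)
  if (isTRUE(config$data$flip_augment)) {
    flipped <- lapply(tr, function(s) {
      f <- flip_lr(s$image, s$labels, axis = 1L)
      s$image <- f$image
      s$labels <- f$labels
      s$id <- paste0(s$id, "-flip")
      s
    })
    tr <- c(tr, flipped)
  }
  patch_sets <- lapply(seq_along(tr), function(i) {
    cand <- enumerate_candidate_patches(tr[[i]]$labels,
                                        config$data$patch_size,
                                        config$data$sample_stride)
    select_training_patches(tr[[i]]$image, tr[[i]]$labels, cand,
                            config$data$patch_size,
                            seed = config$seed + 97L * i)
  })
  spec <- network_spec(variant = config$model$variant,
                       in_channels = config$model$in_channels,
                       num_classes = K,
                       base_channels = config$model$base_channels,
                       dense_layers = config$model$dense_layers,
                       dilation_schedule = config$model$dilation_schedule,
                       dropout_rate = config$model$dropout_rate)
  net <- build_network(spec, seed = config$seed)
  tc <- train_config(batch_size = config$train$batch_size,
                     base_lr = config$train$base_lr,
                     gamma = config$train$gamma,
                     step_size = config$train$step_size,
                     weight_decay = config$train$weight_decay,
                     momentum = config$train$momentum,
                     max_iterations = config$train$max_iterations,
                     seed = config$seed,
                     metric_every = config$train$metric_every,
                     target_dice = target_dice,
                     max_restarts = if (is.null(config$train$max_restarts)) 0L
                                    else config$train$max_restarts)
  fit <- train_network(net, patch_sets, tc)
  ck <- file.path(out_dir, "checkpoint.rds")
  save_checkpoint(net, ck, extra = list(box = box, reference = ref,
                                        n_quantiles = config$data$n_quantiles))
  write.csv(fit$log, file.path(out_dir, "loss_log.csv"), row.names = FALSE)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(checkpoint = ck, log = fit$log, box = box, iterations = fit$iterations)
}

#' Predict subfield labels for one subject
#'
#' Applies the training-time bounding box and histogram matching, runs
#' overlapped sliding-window majority-vote prediction on the crop, embeds
#' the result back on the native grid, and (by default) keeps only the two
#' largest connected components.
#'
#' @param checkpoint path from [run_train()] (or a loaded checkpoint list).
#' @param image 4D (x, y, z, channel) array on the native grid.
#' @param config a [default_config()]-style list.
#' @param postprocess apply the component filter (default from config).
#' @param out_path optional NIfTI output path.
#' @return 3D integer label volume on the native grid.
#' @export
run_predict <- function(checkpoint, image, config = default_config("smoke"),
                        postprocess = NULL, out_path = NULL) {
  ck <- if (is.character(checkpoint)) load_checkpoint(checkpoint) else checkpoint
  box <- ck$extra$box
  cimg <- crop(image, box)
  for (m in 1:2)
    cimg[, , , m] <- histogram_match(cimg[, , , m],
                                     ck$extra$reference[, , , m],
                                     ck$extra$n_quantiles)
  pred <- predict_volume(ck$net, cimg,
                         patch_size = config$inference$patch_size,
                         stride = config$inference$stride,
                         batch_windows = config$inference$batch_windows)
  labels <- uncrop(pred$labels, box)
  do_pp <- if (is.null(postprocess)) isTRUE(config$postprocess$enabled)
           else isTRUE(postprocess)
  if (do_pp)
    labels <- keep_largest_components(labels, config$postprocess$n_keep,
                                      config$postprocess$connectivity)
  if (!is.null(out_path)) write_volume(labels, out_path)
  labels
}

#' Evaluate predictions and write a metric report
#'
#' @param preds,truths lists of 3D label volumes (aligned grids).
#' @param spacing voxel spacing (mm).
#' @param class_names e.g. [subfield_names()].
#' @param out_prefix if given, writes `<prefix>_metrics.csv` (per subject)
#'   and `<prefix>_summary.json` (mean/SD over subjects).
#' @return list: `per_subject` reports and the `summary` data.frame.
#' @export
run_evaluate <- function(preds, truths, spacing = c(1, 1, 1),
                         class_names = NULL, out_prefix = NULL) {
  stopifnot(length(preds) == length(truths))
  reports <- Map(function(p, t)
    evaluate_segmentation(p, t, spacing, class_names), preds, truths)
  summary <- aggregate_reports(reports)
  if (!is.null(out_prefix)) {
    all <- do.call(rbind, Map(function(r, i) transform(r, subject = i),
                              reports, seq_along(reports)))
    write.csv(all, paste0(out_prefix, "_metrics.csv"), row.names = FALSE)
    jsonlite::write_json(summary, paste0(out_prefix, "_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(per_subject = reports, summary = summary)
}
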