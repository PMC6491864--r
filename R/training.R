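# Softmax loss and the optimization schedule: Adam with beta1 = 0.9
# ("momentum"), L2 weight decay 5e-4 coupled into the gradient, base
# learning rate 1e-4 decayed by gamma = 0.1 every 10,000 iterations,
# batches of 5 patches, 60,000 iterations at full scale.

#' Multinomial softmax (cross-entropy) loss over voxels
#'
#' `L = -sum_i sum_k 1{y_i = k} log(exp(z_{k,i}) / sum_j exp(z_{j,i}))`,
#' computed with a numerically stable log-sum-exp. `z` holds the final-layer
#' scores, `y` the true class of each voxel.
#'
#' @param scores numeric array whose 4th dimension (for a 5D (D,H,W,K,B)
#'   map) or 2nd dimension (for an N x K matrix) indexes the K classes.
#' @param labels integer vector/array of true classes in `1..K`, one per
#'   voxel, in the same voxel order as `scores`.
#' @return the total (summed over voxels) loss, a nonnegative scalar.
#' @export
softmax_loss <- function(scores, labels) {
  sl <- .softmax_loss_grad(scores, labels, want_grad = FALSE)
  sl$loss
}

.softmax_loss_grad <- function(scores, labels, want_grad = TRUE) {
  d <- dim(scores)
  if (length(d) == 5L) {
    K <- d[4L]
    z <- matrix(to_clast(scores), ncol = K)
  } else if (length(d) == 2L) {
    K <- d[2L]
    z <- scores
  } else stop("'scores' must be an N x K matrix or a (D,H,W,K,B) array")
  y <- as.integer(labels)
  if (length(y) != nrow(z)) stop("labels do not match the number of voxels")
  if (anyNA(y) || any(y < 1L | y > K))
    stop(sprintf("labels must lie in 1..%d", K))
  if (!all(is.finite(z))) stop("scores must be finite")
  zmax <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  lse <- zmax + log(rowSums(exp(z - zmax)))
  loss <- sum(lse - z[cbind(seq_len(nrow(z)), y)])
  if (!want_grad) return(list(loss = loss))
  p <- exp(z - lse)
  p[cbind(seq_len(nrow(z)), y)] <- p[cbind(seq_len(nrow(z)), y)] - 1
  grad <- if (length(d) == 5L) from_channel_mat(p, d) else p
  list(loss = loss, grad = grad)
}

#' Training configuration
#'
#' Defaults encode the published schedule: Adam, batch size 5, base
#' learning rate 1e-4 decayed by a factor `gamma = 0.1` every 10,000
#' iterations, weight decay 5e-4, first-moment coefficient 0.9, stop at
#' 60,000 iterations.
#'
#' @param batch_size patches per iteration.
#' @param base_lr initial learning rate.
#' @param gamma multiplicative decay factor per step.
#' @param step_size iterations between decays.
#' @param weight_decay L2 penalty coefficient, added to the gradient.
#' @param momentum Adam first-moment coefficient (beta1).
#' @param max_iterations stop after this many updates.
#' @param seed RNG seed for batch sampling, dropout and initialization.
#' @param metric_every compute the training-Dice monitor every this many
#'   iterations (0 disables).
#' @param target_dice stop early once the monitor reaches this value
#'   (`NULL` disables early stopping).
#' @param monitor_patches number of fixed patches the monitor evaluates.
#' @param max_restarts with the monitor active, re-draw the weight
#'   initialization (deterministically, from the running RNG stream) up to
#'   this many times when an attempt exhausts `restart_every` iterations
#'   without reaching `target_dice` — small networks occasionally
#'   initialize into a basin that never leaves the dominant classes, and a
#'   fresh start is cheaper than a longer budget. 0 (default) disables.
#'   The state returned is always the best-monitored one across attempts.
#' @param restart_every iterations granted to each attempt before a
#'   restart may fire.
#' @return an object of class `train_config`.
#' @export
train_config <- function(batch_size = 5L, base_lr = 1e-4, gamma = 0.1,
                         step_size = 10000L, weight_decay = 5e-4,
                         momentum = 0.9, max_iterations = 60000L,
                         seed = 1L, metric_every = 0L, target_dice = NULL,
                         monitor_patches = 10L, max_restarts = 0L,
                         restart_every = 450L) {
  stopifnot(batch_size >= 1, base_lr > 0, gamma > 0, gamma <= 1,
            step_size >= 1, weight_decay >= 0, momentum >= 0, momentum < 1,
            max_iterations >= 1)
  structure(list(batch_size = as.integer(batch_size), base_lr = base_lr,
                 gamma = gamma, step_size = as.integer(step_size),
                 weight_decay = weight_decay, momentum = momentum,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed),
                 metric_every = as.integer(metric_every),
                 target_dice = target_dice,
                 monitor_patches = as.integer(monitor_patches),
                 max_restarts = as.integer(max_restarts),
                 restart_every = as.integer(restart_every)),
            class = "train_config")
}

#' Stepped learning-rate schedule
#'
#' `lr(t) = base_lr * gamma^floor(t / step_size)`; with the defaults the
#' rate starts at 1e-4 and drops tenfold every 10,000 iterations.
#'
#' @param iteration iteration index (0-based), vectorized.
#' @param config a [train_config()].
#' @return learning rate(s).
#' @export
lr_at <- function(iteration, config = train_config()) {
  if (any(iteration < 0)) stop("'iteration' must be >= 0")
  config$base_lr * config$gamma^floor(iteration / config$step_size)
}

## ---- Adam ----

adam_init <- function(net) {
  for (l in net$layers) {
    if (!layer_trainable(l)) next
    for (p in l$par_names) {
      assign(paste0("m_", p), get(p, envir = l) * 0, envir = l)
      assign(paste0("v_", p), get(p, envir = l) * 0, envir = l)
    }
  }
  invisible(net)
}

adam_step <- function(net, lr, config, t, beta2 = 0.999, eps = 1e-8) {
  b1 <- config$momentum
  bc1 <- 1 - b1^t
  bc2 <- 1 - beta2^t
  for (l in net$layers) {
    if (!layer_trainable(l)) next
    for (p in l$par_names) {
      w <- get(p, envir = l)
      g <- get(paste0("g", p), envir = l)
      if (config$weight_decay > 0 && p %in% c("W", "gamma"))
        g <- g + config$weight_decay * w
      m <- b1 * get(paste0("m_", p), envir = l) + (1 - b1) * g
      v <- beta2 * get(paste0("v_", p), envir = l) + (1 - beta2) * g * g
      assign(paste0("m_", p), m, envir = l)
      assign(paste0("v_", p), v, envir = l)
      assign(p, w - lr * (m / bc1) / (sqrt(v / bc2) + eps), envir = l)
    }
  }
  invisible(net)
}

## ---- training loop ----

#' Train a segmentation network on extracted patches
#'
#' Uniform random batches (with replacement, across all subjects' patch
#' sets), softmax loss, Adam updates under the stepped learning-rate
#' schedule. Optionally monitors a foreground-average Dice on a fixed
#' subset of training patches and stops early once `target_dice` is
#' reached.
#'
#' @param net a [build_network()] result.
#' @param patch_sets a single patch set (see [select_training_patches()])
#'   or a list of them, one per training subject.
#' @param config a [train_config()].
#' @param verbose print progress every 50 iterations.
#' @return a list: `net` (trained in place), `log` (data.frame of
#'   iteration, lr, loss, and the Dice monitor where computed), and
#'   `iterations` actually run.
#' @export
train_network <- function(net, patch_sets, config = train_config(),
                          verbose = FALSE) {
  if (inherits(patch_sets, "patch_set")) patch_sets <- list(patch_sets)
  stopifnot(length(patch_sets) >= 1)
  set.seed(config$seed)
  adam_init(net)
  K <- net$spec$num_classes
  counts <- vapply(patch_sets, function(ps) nrow(ps$origins), integer(1))
  if (any(counts < 1L)) stop("every patch set must be non-empty")
  pool <- do.call(rbind, lapply(seq_along(patch_sets), function(s)
    cbind(s, seq_len(counts[s]))))
  monitor_idx <- if (config$metric_every > 0)
    pool[sample.int(nrow(pool), min(config$monitor_patches, nrow(pool))), ,
         drop = FALSE]
  log_rows <- vector("list", config$max_iterations)
  dice_mon <- NA_real_
  iters <- 0L
  best_mon <- -Inf
  best_state <- NULL
  restarts <- 0L
  t0 <- 0L
  for (it in seq_len(config$max_iterations)) {
    pick <- pool[sample.int(nrow(pool), config$batch_size, replace = TRUE), ,
                 drop = FALSE]
    batch <- assemble_batch(patch_sets, pick)
    scores <- network_forward(net, batch$x, training = TRUE)
    sl <- .softmax_loss_grad(scores, batch$y + 1L)
    if (!is.finite(sl$loss))
      stop(sprintf("non-finite loss at iteration %d; aborting", it))
    loss <- sl$loss / length(batch$y)
    zero_grads(net)
    network_backward(net, sl$grad / length(batch$y))
    lr <- lr_at(it - 1L, config)
    adam_step(net, lr, config, t = it - t0)
    iters <- it
    if (config$metric_every > 0 && it %% config$metric_every == 0L) {
      dice_mon <- monitor_dice(net, patch_sets, monitor_idx, K)
      if (!is.null(config$target_dice) && is.finite(dice_mon) &&
          dice_mon >= config$target_dice) {
        log_rows[[it]] <- data.frame(iteration = it, lr = lr, loss = loss,
                                     train_dice = dice_mon)
        break
      }
      if (is.finite(dice_mon) && dice_mon > best_mon) {
        best_mon <- dice_mon
        best_state <- network_state(net)
      }
      if (config$max_restarts > 0L && restarts < config$max_restarts &&
          (it - t0) >= config$restart_every) {
        for (l in net$layers) reinit_layer(l)
        adam_init(net)
        restarts <- restarts + 1L
        t0 <- it
      }
    }
    log_rows[[it]] <- data.frame(iteration = it, lr = lr, loss = loss,
                                 train_dice = if (config$metric_every > 0 &&
                                                  it %% config$metric_every == 0L)
                                   dice_mon else NA_real_)
    if (verbose && it %% 50L == 0L)
      message(sprintf("iter %d  lr %.2g  loss %.4f  dice %.3f",
                      it, lr, loss, dice_mon))
  }
  if (!is.null(best_state) && is.finite(best_mon) && best_mon > 0)
    set_network_state(net, best_state)
  list(net = net, log = do.call(rbind, log_rows[!vapply(log_rows, is.null,
                                                        logical(1))]),
       iterations = iters, best_monitor = if (is.finite(best_mon)) best_mon
                                          else NA_real_)
}

zero_grads <- function(net) {
  for (l in net$layers) zero_layer_grads(l)
  invisible(net)
}

assemble_batch <- function(patch_sets, pick) {
  xs <- vector("list", nrow(pick))
  ys <- vector("list", nrow(pick))
  for (i in seq_len(nrow(pick))) {
    ps <- patch_sets[[pick[i, 1L]]]
    pr <- extract_patch(ps, pick[i, 2L])
    xs[[i]] <- pr$image
    ys[[i]] <- pr$labels
  }
  R <- dim(xs[[1L]])[1:3]
  C <- dim(xs[[1L]])[4L]
  x <- array(unlist(xs, use.names = FALSE), dim = c(R, C, length(xs)))
  y <- array(unlist(ys, use.names = FALSE), dim = c(R, 1L, length(ys)))
  # label order must match the channel-matrix voxel order (D,H,W,B)
  y <- as.integer(to_clast(y))
  list(x = x, y = y)
}

# Foreground-average Dice of eval-mode argmax predictions on fixed patches;
# voxel counts are aggregated over the monitor patches before the Dice
# ratio is formed, then averaged over the foreground classes present in
# the ground truth.
monitor_dice <- function(net, patch_sets, idx, K) {
  inter <- pa <- pb <- numeric(K - 1L)
  for (i in seq_len(nrow(idx))) {
    ps <- patch_sets[[idx[i, 1L]]]
    pr <- extract_patch(ps, idx[i, 2L])
    x <- array(pr$image, dim = c(dim(pr$image), 1L))
    scores <- network_forward(net, x, training = FALSE)
    pred <- max.col(matrix(to_clast(scores), ncol = K), ties.method = "first") - 1L
    truth <- as.integer(pr$labels)
    for (k in seq_len(K - 1L)) {
      inter[k] <- inter[k] + sum(pred == k & truth == k)
      pa[k] <- pa[k] + sum(truth == k)
      pb[k] <- pb[k] + sum(pred == k)
    }
  }
  present <- pa > 0
  if (!any(present)) return(NA_real_)
  mean(2 * inter[present] / (pa[present] + pb[present]))
}


# Re-draw a layer's parameters in place (fresh He-normal weights, unit BN),
# consuming the current RNG stream so restarts stay deterministic.
reinit_layer <- function(l) {
  if (l$type == "conv") {
    l$W <- he_init(l$c_out, l$c_in * l$k^3, fan_in = l$c_in * l$k^3)
    l$b <- numeric(l$c_out)
  } else if (l$type == "deconv") {
    l$W <- he_init(l$c_in, l$c_out * l$k^3,
                   fan_in = l$c_in * l$k^3 / l$stride^3)
    l$b <- numeric(l$c_out)
  } else if (l$type == "bn") {
    l$gamma <- rep(1, l$C)
    l$beta <- numeric(l$C)
    l$run_mean <- numeric(l$C)
    l$run_var <- rep(1, l$C)
  }
  zero_layer_grads(l)
  invisible(l)
}
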