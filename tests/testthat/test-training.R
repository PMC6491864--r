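test_that("softmax loss closed forms: uniform logits and saturated margins", {
  N <- 2 * 2 * 2 * 2  # voxels x batch
  K <- 3
  scores <- array(0, c(2, 2, 2, K, 2))
  y <- rep(1L, N)
  expect_equal(softmax_loss(scores, y), N * log(K), tolerance = 1e-12)

  # a 50-margin on the true class drives the loss to the zero limit
  sat <- array(0, c(2, 2, 2, K, 2))
  sat[, , , 2, ] <- 50
  expect_lt(softmax_loss(sat, rep(2L, N)), 1e-6 * N)
})

test_that("softmax loss matches the direct unstabilized formula on random scores", {
  set.seed(1)
  for (rep in 1:5) {
    z <- array(rnorm(2 * 2 * 2 * 3), c(2, 2, 2, 3, 1))
    y <- sample(1:3, 8, replace = TRUE)
    zm <- matrix(aperm(z, c(1, 2, 3, 5, 4)), ncol = 3)
    direct <- -sum(log(exp(zm[cbind(1:8, y)]) / rowSums(exp(zm))))
    expect_equal(softmax_loss(z, y), direct, tolerance = 1e-6)
  }
})

test_that("loss rejects labels outside 1..K and non-finite scores", {
  z <- array(0, c(2, 2, 2, 3, 1))
  expect_error(softmax_loss(z, rep(4L, 8)), "labels")
  expect_error(softmax_loss(z, rep(0L, 8)), "labels")
  z[1] <- Inf
  expect_error(softmax_loss(z, rep(1L, 8)), "finite")
})

test_that("loss gradient is the softmax-minus-onehot map", {
  set.seed(2)
  z <- array(rnorm(8 * 2), c(2, 2, 2, 2, 1))
  y <- sample(1:2, 8, replace = TRUE)
  sl <- ddunet:::.softmax_loss_grad(z, y)
  zm <- matrix(aperm(z, c(1, 2, 3, 5, 4)), ncol = 2)
  p <- exp(zm) / rowSums(exp(zm))
  p[cbind(1:8, y)] <- p[cbind(1:8, y)] - 1
  gm <- matrix(aperm(sl$grad, c(1, 2, 3, 5, 4)), ncol = 2)
  expect_equal(gm, p, tolerance = 1e-10)
})

test_that("stepped learning-rate schedule follows the closed form", {
  cfg <- train_config()
  expect_equal(lr_at(0, cfg), 1e-4)
  expect_equal(lr_at(9999, cfg), 1e-4)
  expect_equal(lr_at(10000, cfg), 1e-5)
  expect_equal(lr_at(59999, cfg), 1e-9)
  expect_error(lr_at(-1, cfg), ">= 0")
  expect_error(train_config(gamma = 0), "gamma")
})

test_that("a short training run decreases the loss and is seed-reproducible", {
  set.seed(3)
  lab <- array(0L, c(16, 16, 16))
  lab[5:12, 5:12, 5:12] <- 1L
  img <- array(rnorm(16^3 * 2, sd = 0.1), c(16, 16, 16, 2))
  img[, , , 1] <- img[, , , 1] + as.numeric(lab) * 2
  cand <- enumerate_candidate_patches(lab, 8, 2)
  ps <- select_training_patches(img, lab, cand, 8, seed = 1)

  run_once <- function() {
    net <- build_network(network_spec("unet3d", num_classes = 2L,
                                      base_channels = 2L), seed = 4)
    train_network(net, ps, train_config(batch_size = 2, base_lr = 1e-3,
                                        max_iterations = 40, seed = 5))
  }
  f1 <- run_once()
  expect_equal(f1$iterations, 40L)
  expect_true(all(is.finite(f1$log$loss)))
  # smoothed early-vs-late comparison on the overfit fixture
  expect_lt(mean(tail(f1$log$loss, 10)), mean(head(f1$log$loss, 10)))
  # bitwise-reproducible trajectory under a fixed seed
  f2 <- run_once()
  expect_identical(f1$log$loss, f2$log$loss)
})

test_that("training aborts on non-finite inputs with a diagnostic", {
  lab <- array(0L, c(10, 10, 10)); lab[5, 5, 5] <- 1L
  img <- array(rnorm(1000 * 2), c(10, 10, 10, 2))
  img[5, 5, 5, 1] <- Inf  # poisoned voxel propagates to the scores
  cand <- enumerate_candidate_patches(lab, 8, 2)
  ps <- select_training_patches(img, lab, cand, 8, seed = 1)
  net <- build_network(network_spec("unet3d", num_classes = 2L,
                                    base_channels = 2L), seed = 1)
  expect_error(
    train_network(net, ps, train_config(batch_size = 1, max_iterations = 3,
                                        seed = 1)),
    "finite|abort")
})
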