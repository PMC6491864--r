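test_that("window origins: single window, end alignment, full coverage", {
  expect_equal(nrow(window_origins(c(24, 24, 24), 24, 8)), 1L)

  org <- window_origins(c(40, 40, 40), 24, 8)
  # per axis: regular lattice 1, 9 plus the end-aligned origin 17
  expect_equal(sort(unique(org[, 1])), c(1L, 9L, 17L))

  covered <- logical(40)
  for (o in unique(org[, 1])) covered[o:(o + 23)] <- TRUE
  expect_true(all(covered))

  expect_error(window_origins(c(10, 10, 10), 24, 8), "exceeds")
})

test_that("every voxel is covered by >= 1 and <= (patch/stride)^3 windows", {
  dims <- c(30, 28, 26)
  org <- window_origins(dims, 16, 8)
  cover <- array(0L, dims)
  for (r in seq_len(nrow(org))) {
    o <- org[r, ]
    idx <- lapply(1:3, function(a) o[a]:(o[a] + 15))
    cover[idx[[1]], idx[[2]], idx[[3]]] <- cover[idx[[1]], idx[[2]], idx[[3]]] + 1L
  }
  expect_true(all(cover >= 1L))
  expect_true(all(cover <= (16 / 8 + 1)^3))  # end alignment adds at most one
})

test_that("argmax labeling: examples, ties and one-hot inversion", {
  p <- array(0, c(1, 1, 1, 3))
  p[1, 1, 1, ] <- c(0.1, 0.7, 0.2)
  expect_equal(as.integer(argmax_label(p)), 1L)  # class k=2, stored as 1

  u <- array(1 / 3, c(1, 1, 1, 3))
  expect_equal(as.integer(argmax_label(u)), 0L)  # tie -> smallest index

  set.seed(1)
  lab <- array(sample(0:3, 4^3, replace = TRUE), c(4, 4, 4))
  oh <- array(0, c(4, 4, 4, 4))
  oh[cbind(which(lab >= 0, arr.ind = TRUE), as.integer(lab) + 1L)] <- 1
  expect_equal(argmax_label(oh), array(as.integer(lab), dim(lab)))

  bad <- u; bad[1] <- NaN
  expect_error(argmax_label(bad), "NaN")
  expect_error(argmax_label(array(2, c(1, 1, 1, 3))), "normalized")
})

test_that("single-window prediction equals the direct argmax of one forward", {
  net <- build_network(tiny_spec("dunet", K = 4L), seed = 1)
  set.seed(2)
  img <- array(rnorm(16^3 * 2), c(16, 16, 16, 2))
  pred <- predict_volume(net, img, patch_size = 16, stride = 8)
  x <- array(img, c(16, 16, 16, 2, 1))
  scores <- network_forward(net, x, training = FALSE)
  direct <- argmax_label(array(scores, c(16, 16, 16, 4)), normalized = FALSE)
  expect_equal(pred$labels, direct)
  expect_true(all(apply(pred$votes, 1:3, sum) == 1))
})

test_that("majority-vote fusion: agreement, coverage and batching invariance", {
  net <- build_network(tiny_spec("resdunet", K = 3L), seed = 3)
  set.seed(4)
  img <- array(rnorm(24 * 16 * 16 * 2), c(24, 16, 16, 2))
  p1 <- predict_volume(net, img, patch_size = 16, stride = 8,
                       batch_windows = 1)
  p2 <- predict_volume(net, img, patch_size = 16, stride = 8,
                       batch_windows = 4)
  expect_equal(p1$labels, p2$labels)  # window grouping cannot matter
  expect_equal(p1$votes, p2$votes)
  # coverage: vote totals equal window multiplicity, never zero
  tot <- apply(p1$votes, 1:3, sum)
  expect_true(all(tot >= 1))
})

test_that("vote ties resolve to the smaller class index", {
  votes <- array(0L, c(2, 2, 2, 3))
  votes[, , , 2] <- 1L
  votes[, , , 3] <- 1L  # classes 1 and 2 tied, background outvoted
  vm <- matrix(votes, ncol = 3)
  lab <- array(max.col(vm, ties.method = "first") - 1L, c(2, 2, 2))
  expect_true(all(lab == 1L))
})
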