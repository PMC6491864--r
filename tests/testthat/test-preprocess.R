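test_that("bounding box: margin arithmetic and clamping", {
  lab <- array(0L, c(64, 64, 64))
  lab[11:21, 11:21, 11:21] <- 1L  # foreground spans 11..21 per axis
  box <- compute_bounding_box(lab, margin = 32)
  expect_equal(unname(box["min", ]), c(1L, 1L, 1L))   # clamped at the face
  expect_equal(unname(box["max", ]), c(53L, 53L, 53L))
  expect_equal(dim(crop(lab, box)), c(53L, 53L, 53L))

  box0 <- compute_bounding_box(lab, margin = 0)
  expect_equal(unname(box0["min", ]), c(11L, 11L, 11L))
  expect_equal(unname(box0["max", ]), c(21L, 21L, 21L))

  expect_error(compute_bounding_box(array(0L, c(8, 8, 8))), "foreground")
})

test_that("bounding box unions foreground across several volumes", {
  a <- array(0L, c(16, 16, 16)); a[3, 4, 5] <- 1L
  b <- array(0L, c(16, 16, 16)); b[12, 10, 2] <- 2L
  box <- compute_bounding_box(list(a, b), margin = 1)
  expect_equal(unname(box["min", ]), c(2L, 3L, 1L))
  expect_equal(unname(box["max", ]), c(13L, 11L, 6L))
})

test_that("crop/uncrop: identity on full box, inverse on the interior", {
  set.seed(1)
  vol <- array(rnorm(10 * 12 * 14), c(10, 12, 14))
  lab <- array(0L, dim(vol)); lab[4:6, 5:8, 6:9] <- 1L
  full <- compute_bounding_box(lab, margin = 100)   # clamps to full extent
  expect_equal(crop(vol, full), vol)

  box <- compute_bounding_box(lab, margin = 1)
  cr <- crop(lab, box)
  back <- uncrop(cr, box)
  expect_equal(back, lab)                            # interior restored
  expect_true(all(back[1, , ] == 0))                 # background outside

  bad <- box
  bad["max", 1] <- 99L
  expect_error(crop(vol, bad), "exceeds")

  # 4D channel volumes crop along spatial axes only
  vol4 <- array(rnorm(10 * 12 * 14 * 2), c(10, 12, 14, 2))
  expect_equal(dim(crop(vol4, box))[4], 2L)
})

test_that("histogram matching: identity, quantile agreement, monotonicity", {
  set.seed(2)
  mov <- array(rgamma(24^3, shape = 2, scale = 20), c(24, 24, 24))
  ref <- array(rnorm(24^3, 300, 40), c(24, 24, 24))

  self <- histogram_match(mov, mov)
  expect_lt(max(abs(self - mov)), diff(range(mov)) / 100)

  out <- histogram_match(mov, ref)
  qs <- seq(0.01, 0.99, by = 0.01)
  binw <- diff(range(ref)) / 255
  expect_lt(max(abs(quantile(out, qs) - quantile(ref, qs))), binw * 2)

  ord <- order(as.numeric(mov))
  expect_true(all(diff(as.numeric(out)[ord]) >= 0))

  expect_warning(cst <- histogram_match(array(5, c(4, 4, 4)), ref), "constant")
  expect_equal(unique(as.numeric(cst)), stats::median(ref))
})

test_that("histogram matching is idempotent to within a bin", {
  set.seed(3)
  mov <- array(runif(20^3, 0, 100), c(20, 20, 20))
  ref <- array(rexp(20^3, 0.02), c(20, 20, 20))
  once <- histogram_match(mov, ref)
  twice <- histogram_match(once, ref)
  expect_lt(max(abs(twice - once)), diff(range(ref)) / 255)
})

test_that("left-right flip is an involution preserving per-class counts", {
  set.seed(4)
  img <- array(rnorm(8 * 10 * 12 * 2), c(8, 10, 12, 2))
  lab <- array(sample(0:3, 8 * 10 * 12, replace = TRUE), c(8, 10, 12))
  f1 <- flip_lr(img, lab, axis = 1)
  expect_equal(as.integer(table(f1$labels)), as.integer(table(lab)))
  expect_equal(sum(f1$labels != 0), sum(lab != 0))
  f2 <- flip_lr(f1$image, f1$labels, axis = 1)
  expect_identical(f2$image, img)
  expect_identical(f2$labels, lab)
  expect_warning(flip_lr(img, lab), "axis 1")
})
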