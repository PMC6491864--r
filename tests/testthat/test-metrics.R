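test_that("dice: identity, disjoint and the half-overlap cube fixture", {
  a <- array(0L, c(10, 10, 10))
  a[2:3, 2:3, 2:3] <- 1L
  expect_equal(dice(a, a, 1), 1)

  b <- array(0L, c(10, 10, 10))
  b[6:7, 6:7, 6:7] <- 1L
  expect_equal(dice(a, b, 1), 0)

  # two 8-voxel cubes overlapping in 4 voxels: 2*4/(8+8) = 0.5
  a2 <- array(0L, c(10, 10, 10)); a2[2:3, 2:3, 2:3] <- 1L
  b2 <- array(0L, c(10, 10, 10)); b2[2:3, 2:3, 3:4] <- 1L
  expect_equal(sum(a2 == 1 & b2 == 1), 4)
  expect_equal(dice(a2, b2, 1), 0.5)

  expect_true(is.na(dice(a * 0L, b * 0L, 1)))  # absent from both: undefined
  expect_equal(dice(a, b, 1), dice(b, a, 1))   # symmetry
})

test_that("assd: two-point fixture scales linearly with spacing", {
  a <- array(0L, c(6, 6, 6)); a[1, 1, 1] <- 1L
  b <- array(0L, c(6, 6, 6)); b[4, 1, 1] <- 1L
  expect_equal(assd(a, b, 1, spacing = c(1, 1, 1)), 3.0)
  expect_equal(assd(a, b, 1, spacing = c(0.8, 0.8, 0.8)), 2.4)
  expect_equal(assd(a, a, 1), 0)
  expect_true(is.na(assd(a, b * 0L, 1)))       # empty in one: undefined
  expect_equal(assd(a, b, 1), assd(b, a, 1))   # symmetry
})

test_that("assd agrees with the brute-force double-loop oracle on random masks", {
  set.seed(1)
  for (rep in 1:10) {
    a <- array(0L, c(7, 7, 7))
    b <- array(0L, c(7, 7, 7))
    oa <- sample(1:4, 3); ob <- sample(1:4, 3)
    a[oa[1]:(oa[1] + 2), oa[2]:(oa[2] + 2), oa[3]:(oa[3] + 2)] <- 1L
    b[ob[1]:(ob[1] + 3), ob[2]:(ob[2] + 2), ob[3]:(ob[3] + 1)] <- 1L
    sp <- sample(c(0.5, 0.8, 1.0), 3, replace = TRUE)
    expect_equal(assd(a, b, 1, sp), brute_assd(a, b, 1, sp),
                 tolerance = 1e-10)
  }
})

test_that("evaluation report: perfect prediction, composition, missing classes", {
  set.seed(2)
  truth <- array(0L, c(12, 12, 12))
  truth[3:6, 3:6, 3:6] <- 1L
  truth[8:10, 8:10, 8:10] <- 2L
  rep1 <- evaluate_segmentation(truth, truth, class_names = c("1" = "CA1"))
  expect_equal(rep1$dice[rep1$name == "Average"], 1)
  expect_equal(rep1$assd[rep1$name == "Average"], 0)
  expect_equal(rep1$name[1], "CA1")

  pred <- truth
  pred[3, 3, 3] <- 0L
  rep2 <- evaluate_segmentation(pred, truth)
  expect_equal(rep2$dice[rep2$class == 1 & !is.na(rep2$class)],
               dice(truth, pred, 1))
  expect_equal(rep2$assd[rep2$class == 2 & !is.na(rep2$class)],
               assd(truth, pred, 2))

  # class present in truth but absent from prediction: dice 0, assd missing
  pred2 <- truth
  pred2[pred2 == 2L] <- 0L
  rep3 <- evaluate_segmentation(pred2, truth)
  expect_equal(rep3$dice[rep3$class == 2 & !is.na(rep3$class)], 0)
  expect_true(is.na(rep3$assd[rep3$class == 2 & !is.na(rep3$class)]))
  # the average still aggregates what is defined
  expect_false(is.na(rep3$dice[rep3$name == "Average"]))

  expect_error(evaluate_segmentation(truth, array(0L, c(6, 6, 6))), "match")
})

test_that("multi-subject aggregation reproduces direct mean/SD arithmetic", {
  set.seed(3)
  reports <- lapply(1:3, function(i) {
    truth <- array(0L, c(10, 10, 10))
    truth[2:5, 2:5, 2:5] <- 1L
    pred <- truth
    drop <- which(truth == 1L)[seq_len(6 * i)]
    pred[drop] <- 0L
    evaluate_segmentation(pred, truth)
  })
  agg <- aggregate_reports(reports)
  d1 <- vapply(reports, function(r) r$dice[r$class == 1 & !is.na(r$class)],
               numeric(1))
  expect_equal(agg$dice_mean[agg$name == "1"], mean(d1))
  expect_equal(agg$dice_sd[agg$name == "1"], sd(d1))
})
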