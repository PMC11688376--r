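test_that("region scores hit the exact values on constructed overlaps", {
  gt <- matrix(0, 8, 8); gt[3:6, 2:5] <- 1        # 4x4 block
  pred <- matrix(0, 8, 8); pred[3:6, 4:7] <- 1    # shifted 2 columns
  s <- region_scores(gt, pred)
  expect_equal(s$iou, 8 / 24, tolerance = 1e-12)
  expect_equal(s$dice, 0.5, tolerance = 1e-12)
  expect_equal(s$recall, 0.5, tolerance = 1e-12)
  expect_equal(s$precision, 0.5, tolerance = 1e-12)

  expect_equal(unlist(region_scores(gt, gt)), c(iou = 1, dice = 1, recall = 1,
                                                precision = 1))
  disj <- matrix(0, 8, 8); disj[1, 8] <- 1
  expect_equal(sum(unlist(region_scores(gt, disj))), 0)
  expect_error(region_scores(gt, matrix(0, 4, 4)), "dimensions")
})

test_that("empty-mask conventions are honored", {
  e <- matrix(0, 5, 5)
  f <- e; f[2, 2] <- 1
  expect_equal(unlist(region_scores(e, e)), c(iou = 1, dice = 1, recall = 1,
                                              precision = 1))
  expect_equal(sum(unlist(region_scores(e, f))), 0)
  expect_equal(sum(unlist(region_scores(f, e))), 0)
})

test_that("soft losses evaluate their closed-form examples", {
  y <- matrix(0, 10, 10); y[1:5, 1:5] <- 1  # 25% foreground over 100 px
  p <- matrix(0.5, 10, 10)
  expect_equal(dice_loss(p, y, smooth = 0), 1 - 25 / 75, tolerance = 1e-12)
  expect_equal(dice_loss(y, y, smooth = 0), 0, tolerance = 1e-12)
  expect_equal(dice_loss(1 - y, y, smooth = 0), 1, tolerance = 1e-12)
  expect_equal(jaccard_loss(y, y, smooth = 0), 0, tolerance = 1e-12)
  expect_equal(jaccard_loss(1 - y, y, smooth = 0), 1, tolerance = 1e-12)

  expect_equal(bce_loss(matrix(0.5, 4, 4), matrix(c(0, 1), 4, 4)),
               log(2), tolerance = 1e-12)
  y2 <- matrix(c(1, 0, 1, 0), 2, 2)
  p2 <- matrix(c(0.9, 0.1, 0.8, 0.3), 2, 2)
  expect_equal(bce_loss(p2, y2),
               -(log(0.9) + log(0.9) + log(0.8) + log(0.7)) / 4,
               tolerance = 1e-12)
  expect_error(dice_loss(matrix(1.2, 2, 2), matrix(1, 2, 2)), "0, 1")
})

test_that("loss/metric identities hold across random binary pairs", {
  set.seed(123)
  for (i in 1:100) {
    gt <- matrix(rbinom(64, 1, runif(1, 0.2, 0.8)), 8, 8)
    pr <- matrix(rbinom(64, 1, runif(1, 0.2, 0.8)), 8, 8)
    s <- region_scores(gt, pr)
    expect_equal(s$dice, 2 * s$iou / (1 + s$iou), tolerance = 1e-12)
    expect_equal(dice_loss(pr, gt, smooth = 0),
                 if (sum(gt) + sum(pr) > 0) 1 - s$dice else 0, tolerance = 1e-12)
    expect_equal(jaccard_loss(pr, gt, smooth = 0),
                 if (sum(gt) + sum(pr) > 0) 1 - s$iou else 0, tolerance = 1e-12)
    # symmetry of the symmetric metrics, duality of the directed ones
    sw <- region_scores(pr, gt)
    expect_equal(s$iou, sw$iou)
    expect_equal(s$dice, sw$dice)
    expect_equal(s$recall, sw$precision)
  }
})

test_that("bce is minimized at the ground truth", {
  set.seed(9)
  y <- matrix(rbinom(36, 1, 0.5), 6, 6)
  ref <- bce_loss(y, y)
  for (i in 1:10) {
    alt <- matrix(runif(36), 6, 6)
    expect_gte(bce_loss(alt, y), ref)
  }
})

test_that("consensus is the pixel-wise AND", {
  a <- matrix(0, 6, 6); a[2:5, 2:5] <- 1
  b <- matrix(0, 6, 6); b[3:5, 2:4] <- 1
  c_ <- matrix(0, 6, 6); c_[3:4, 3:4] <- 1
  expect_equal(consensus_mask(list(a, a, a)), as_binary_mask(a))
  expect_equal(sum(consensus_mask(list(a, matrix(0, 6, 6)))), 0)
  expect_equal(consensus_mask(list(a, b, c_)), as_binary_mask(c_))  # nested sets
  expect_error(consensus_mask(list(a)), "at least 2")
  expect_error(consensus_mask(list(a, matrix(0, 3, 3))), "dimensions")
})

test_that("evaluate_masks reports per-pair rows and a mean/sd summary", {
  gt <- list(matrix(c(0, 1), 4, 4), matrix(c(1, 0), 4, 4))
  ev <- evaluate_masks(gt, gt)
  expect_equal(nrow(ev$scores), 2)
  expect_equal(ev$summary$dice_mean, 1)
  expect_equal(ev$summary$iou_sd, 0)
})
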