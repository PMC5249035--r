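test_that("boundary recall: perfect, empty-prediction and error cases", {
  set.seed(70)
  gt <- LabelMap(random_label_map(32, 32, 5))
  expect_equal(boundaryRecall(gt, gt, 2), 1.0)
  single <- LabelMap(matrix(1L, 32, 32))
  expect_equal(boundaryRecall(single, gt, 2), 0.0)
  expect_error(boundaryRecall(gt, single, 2), "no ground-truth edges")
})

test_that("boundary recall matches the window-scan oracle and grows with d", {
  set.seed(71)
  for (t in 1:10) {
    pred <- random_label_map(32, 32, sample(3:10, 1))
    gt <- random_label_map(32, 32, sample(3:10, 1))
    lp <- LabelMap(pred); lg <- LabelMap(gt)
    expect_equal(boundaryRecall(lp, lg, 2), oracle_boundary_recall(pred, gt, 2))
    expect_lte(boundaryRecall(lp, lg, 1), boundaryRecall(lp, lg, 2))
    expect_lte(boundaryRecall(lp, lg, 2), boundaryRecall(lp, lg, 4))
  }
})

test_that("under-segmentation error: zero at identity, 1 for one blob over halves", {
  set.seed(72)
  gt <- LabelMap(random_label_map(32, 32, 6))
  expect_equal(underSegmentationError(gt, gt), 0)
  halves <- LabelMap(matrix(rep(c(1L, 2L), each = 16 * 32), 32, 32))
  one <- LabelMap(matrix(1L, 32, 32))
  expect_equal(underSegmentationError(one, halves), 1.0)
  # older flood-style variant: also 0 at identity, never below the
  # corrected min formulation
  expect_equal(underSegmentationError(gt, gt, variant = "flood"), 0)
  pred <- LabelMap(random_label_map(32, 32, 7))
  expect_gte(underSegmentationError(pred, gt, variant = "flood"),
             underSegmentationError(pred, gt))
})

test_that("under-segmentation error matches the double-loop oracle", {
  set.seed(73)
  for (t in 1:10) {
    pred <- random_label_map(32, 32, sample(4:12, 1))
    gt <- random_label_map(32, 32, sample(3:8, 1))
    expect_equal(underSegmentationError(LabelMap(pred), LabelMap(gt)),
                 oracle_use(pred, gt), tolerance = 1e-12)
  }
})

test_that("Dice coefficient follows the definition", {
  H <- 20; W <- 20
  X <- matrix(FALSE, H, W); X[1:10, 1:10] <- TRUE
  expect_equal(diceCoefficient(X, X), 1)
  Y <- matrix(FALSE, H, W); Y[3:12, 1:10] <- TRUE  # |X|=|Y|=100, overlap 80
  expect_equal(diceCoefficient(X, Y), 0.8)
  expect_equal(diceCoefficient(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)
  # symmetry and identity-of-indiscernibles on random masks
  set.seed(74)
  for (t in 1:20) {
    A <- matrix(runif(H * W) < 0.4, H, W)
    B <- matrix(runif(H * W) < 0.4, H, W)
    expect_equal(diceCoefficient(A, B), diceCoefficient(B, A))
    expect_equal(diceCoefficient(A, B), oracle_dice(A, B))
    expect_true(diceCoefficient(A, B) >= 0 && diceCoefficient(A, B) <= 1)
  }
})

test_that("median Dice matches the exhaustive matching oracle", {
  set.seed(75)
  gt <- random_label_map(32, 32, 5)
  expect_equal(medianDice(LabelMap(gt), LabelMap(gt))$medDSC, 1.0)
  for (t in 1:10) {
    pred <- random_label_map(32, 32, sample(4:12, 1))
    gt <- random_label_map(32, 32, sample(3:8, 1))
    got <- medianDice(LabelMap(pred), LabelMap(gt))
    want <- oracle_med_dsc(pred, gt)
    expect_equal(got$medDSC, want$medDSC, tolerance = 1e-12)
    expect_equal(got$table$dsc, unname(want$dsc), tolerance = 1e-12)
  }
})

test_that("DSC_X is the fraction at or above X/100 and is non-increasing", {
  expect_equal(dscAtX(c(1, 1, 1), 90), 1)
  expect_equal(dscAtX(c(0.8, 0.7, 0.6, 0.9), 75), 0.5)
  expect_error(dscAtX(numeric(0), 75), "empty")
  set.seed(76)
  v <- runif(30)
  xs <- seq(0, 100, 10)
  d <- vapply(xs, function(X) dscAtX(v, X), numeric(1))
  expect_true(all(diff(d) <= 0))
})

test_that("evaluation report aggregates all metrics coherently", {
  set.seed(77)
  pred <- LabelMap(random_label_map(48, 48, 10))
  gt <- LabelMap(random_label_map(48, 48, 6))
  rep <- evaluateSegmentation(pred, gt, K_used = 10L)
  expect_s3_class(rep, "EvalReport")
  expect_equal(rep$medDSC, median(rep$dsc_per_segment$dsc))
  expect_true(all(diff(rep$dsc_x) <= 0))
  expect_true(all(rep$dsc_x >= 0 & rep$dsc_x <= 1))
  expect_identical(rep$dsc_per_segment$good, rep$dsc_per_segment$dsc > 0.70)
})
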