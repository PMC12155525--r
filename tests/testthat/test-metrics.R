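test_that("IoU on hand-counted images matches the by-hand fractions", {
  c1 <- 3L; v <- voidLabel(scheme)
  # 2x2: truth {c,c,v,v}, pred {c,v,v,v}: intersection 1, union 2
  truth <- matrix(c(c1, c1, v, v), 2, 2)
  pred <- matrix(c(c1, v, v, v), 2, 2)
  m <- metrics2D(pred, truth)
  expect_equal(unname(m$perClassIoU[labelName(scheme, c1)]), 0.5)
  expect_equal(m$pixelAccuracy, 3 / 4)

  # 4x4 with three classes, counted by hand
  a <- 1L; b <- 2L
  truth4 <- matrix(c(a, a, a, a,  b, b, b, b,  v, v, v, v,  v, v, v, v), 4, 4)
  pred4  <- matrix(c(a, a, b, b,  b, b, b, v,  v, v, v, v,  a, v, v, v), 4, 4)
  m4 <- metrics2D(pred4, truth4)
  expect_equal(unname(m4$perClassIoU[labelName(scheme, a)]), 2 / 5)
  expect_equal(unname(m4$perClassIoU[labelName(scheme, b)]), 1 / 2)
  expect_equal(unname(m4$perClassIoU[labelName(scheme, v)]), 7 / 9)
})

test_that("perfect and disjoint predictions give IoU 1 and 0", {
  truth <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  m <- metrics2D(truth, truth)
  expect_true(all(m$perClassIoU[!is.na(m$perClassIoU)] == 1))
  expect_equal(m$pixelAccuracy, 1)
  pred <- matrix(c(2L, 2L, 1L, 1L), 2, 2)
  m0 <- metrics2D(pred, truth)
  expect_true(all(m0$perClassIoU[!is.na(m0$perClassIoU)] == 0))
})

test_that("IoU is symmetric in prediction and truth per class", {
  set.seed(2)
  pred <- matrix(sample(c(0L, 1L, 27L), 64, TRUE), 8, 8)
  truth <- matrix(sample(c(0L, 1L, 27L), 64, TRUE), 8, 8)
  a <- metrics2D(pred, truth)$perClassIoU
  b <- metrics2D(truth, pred)$perClassIoU
  expect_equal(a, b)
})

test_that("classes absent from both sides are excluded from the mean", {
  truth <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  m <- metrics2D(truth, truth)
  expect_true(is.na(m$perClassIoU["rugae"]))
  expect_equal(m$meanIoU, 1)
})

test_that("adult-teeth mean IoU covers only permanent non-third-molar classes", {
  thirdMolar <- labelId(scheme, "left third molar")
  primary <- labelId(scheme, "left primary canine")
  perm <- labelId(scheme, "left canine")
  truth <- matrix(c(thirdMolar, primary, perm, rugaeLabel(scheme)), 2, 2)
  pred <- matrix(c(thirdMolar, primary, voidLabel(scheme), rugaeLabel(scheme)), 2, 2)
  m <- metrics2D(pred, truth)
  # only 'left canine' is an adult tooth here, and it was missed entirely
  expect_equal(m$adultTeethMeanIoU, 0)
  expect_gt(m$meanIoU, 0)
})

test_that("size mismatch is an error", {
  expect_error(metrics2D(matrix(0L, 2, 2), matrix(0L, 3, 3)), "differ")
})

test_that("dataset metrics average per-image means, not pooled pixels", {
  # construct two images whose pooled-pixel mIoU differs from the
  # average of the two per-image means
  big <- matrix(1L, 10, 10)                      # class 1 everywhere
  bigPred <- big; bigPred[1:5, ] <- 2L            # half right
  small <- matrix(2L, 2, 2)
  smallPred <- small                              # perfect
  m1 <- metrics2D(bigPred, big)
  m2 <- metrics2D(smallPred, small)
  dm <- datasetMetrics(list(list(pred = bigPred, truth = big),
                            list(pred = smallPred, truth = small)))
  expect_equal(dm$meanIoU, mean(c(m1$meanIoU, m2$meanIoU)))

  pooledPred <- c(as.vector(bigPred), as.vector(smallPred))
  pooledTruth <- c(as.vector(big), as.vector(small))
  pooled <- metrics3D(pooledPred, pooledTruth)$meanIoU
  expect_false(isTRUE(all.equal(dm$meanIoU, pooled)))

  # one image: dataset metrics equal the per-image metrics
  dm1 <- datasetMetrics(list(list(pred = bigPred, truth = big)))
  expect_equal(dm1$meanIoU, m1$meanIoU)
  expect_equal(dm1$pixelAccuracy, m1$pixelAccuracy)
  # two mean IoUs of 0.4 and 0.8 average to 0.6 by construction
  expect_equal(mean(c(0.4, 0.8)), 0.6)
  expect_error(datasetMetrics(list()), "empty")
})

test_that("precision is the correctly-detected share of predicted pixels", {
  truth <- matrix(c(1L, 1L, 1L, 0L), 2, 2)
  pred <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  m <- metrics2D(pred, truth)
  # class 1: predicted 2, correct 2 -> 1; void: predicted 2, correct 1 -> 0.5
  expect_equal(m$precision, mean(c(1, 0.5)))
})

test_that("vertex-level metrics mirror the pixel definition", {
  truth <- c(rep(4L, 10), rep(0L, 10))
  pred <- truth
  pred[1:5] <- 0L               # half of class 4 flipped to void
  m <- metrics3D(pred, truth)
  expect_equal(unname(m$perClass[labelName(scheme, 4L)]), 0.5)
  expect_error(metrics3D(1L, c(1L, 2L)), "length")
})
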