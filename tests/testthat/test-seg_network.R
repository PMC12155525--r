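# the tiny configs here are chosen so a full forward/backward runs in
# milliseconds; correctness, not capacity, is under test

test_that("configs validate their invariants", {
  expect_error(segnetConfig(nClasses = 1L), "nClasses")
  expect_error(segnetConfig(inputSize = 50L), "divisible")
  expect_error(trainConfig(learningRate = 0), "positive")
  expect_error(trainConfig(decay = 1.5), "decay")
  full <- segnetConfig(fullScale = TRUE)
  expect_equal(sum(full$convsPerBlock), 13L)   # 13-convolution encoder
})

test_that("forward pass produces per-pixel distributions of the right shape", {
  cfg <- segnetConfig(inputSize = 16L, nClasses = 5L, channels = c(4L, 8L))
  model <- buildSegNet(cfg, seed = 2, classIds = c(0L, 1L, 2L, 3L, 27L))
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  fw <- PalateSeg:::.segnetForward(model, x, train = FALSE)
  probs <- PalateSeg:::softmaxProbs(fw$logits)
  expect_equal(dim(probs), c(16L, 16L, 5L))
  sums <- apply(probs, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
})

test_that("attention placements change the graph but not the class count", {
  mk <- function(att) buildSegNet(segnetConfig(inputSize = 16L, nClasses = 4L,
                                               channels = c(4L, 6L),
                                               attention = att),
                                  seed = 1, classIds = 0:3)
  mNone <- mk("none"); mEnd <- mk("end"); mCenter <- mk("center")
  expect_null(mNone$params$att)
  # end gates the full-resolution feature (4 ch), center the bottleneck (6 ch)
  expect_equal(nrow(mEnd$params$att$ch$W1), 4L)
  expect_equal(nrow(mCenter$params$att$ch$W1), 6L)
  expect_false(countParameters(mEnd) == countParameters(mCenter))
  # attention-off is a strict subgraph: same non-attention parameter count
  expect_equal(countParameters(mNone),
               countParameters(mEnd) -
                 sum(lengths(lapply(mEnd$params$att$ch, as.vector))) -
                 length(mEnd$params$att$sp$W) - 1L)
})

test_that("attention with unit weights is the identity; gates scale output", {
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  expect_equal(channelAttention(x, weights = rep(1, 3)), x)
  expect_equal(spatialAttention(x, weights = matrix(1, 8, 8)), x)
  # zero input stays zero through multiplicative gating
  z <- array(0, c(8, 8, 3))
  p <- list(W1 = matrix(rnorm(6), 3, 2), W2 = matrix(rnorm(6), 2, 3))
  expect_equal(channelAttention(z, p), z)
  # shape preserved and constant rows scale by the spatial map
  w <- matrix(runif(64), 8, 8)
  xc <- array(rep(1, 8 * 8 * 3), c(8, 8, 3))
  out <- spatialAttention(xc, weights = w)
  expect_equal(dim(out), dim(xc))
  expect_equal(out[, , 2], w)
  # learned channel gates attenuate: |output| <= |input| elementwise
  xin <- array(runif(192), c(8, 8, 3))
  g <- channelAttention(xin, p)
  expect_true(all(abs(g) <= abs(xin) + 1e-12))
})

test_that("analytic gradients match finite differences", {
  cfg <- segnetConfig(inputSize = 8L, nClasses = 3L, channels = c(3L, 4L),
                      attention = "end")
  model <- buildSegNet(cfg, seed = 3, classIds = 0:2)
  set.seed(5)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  y <- matrix(sample(1:3, 64, TRUE), 8, 8)
  fw <- PalateSeg:::.segnetForward(model, x, train = TRUE)
  sl <- PalateSeg:::softmaxLoss(fw$logits, y)
  g <- PalateSeg:::.segnetBackward(model, fw$caches, sl$dlogits)
  lossWith <- function(params) {
    m2 <- model; m2$params <- params
    f2 <- PalateSeg:::.segnetForward(m2, x, train = TRUE)
    PalateSeg:::softmaxLoss(f2$logits, y)$loss
  }
  eps <- 1e-5
  checks <- list(
    list(get = function(P) P$head$W, set = function(P, v) { P$head$W <- v; P },
         grad = g$head$W),
    list(get = function(P) P$enc[[1]][[1]]$W,
         set = function(P, v) { P$enc[[1]][[1]]$W <- v; P },
         grad = g$enc[[1]][[1]]$W),
    list(get = function(P) P$dec[[2]]$up$gamma,
         set = function(P, v) { P$dec[[2]]$up$gamma <- v; P },
         grad = g$dec[[2]]$up$gamma),
    list(get = function(P) P$att$sp$W,
         set = function(P, v) { P$att$sp$W <- v; P },
         grad = g$att$sp$W)
  )
  set.seed(6)
  for (ck in checks) {
    W <- ck$get(model$params)
    for (i in sample(length(W), 3)) {
      Wp <- W; Wp[i] <- W[i] + eps
      Wm <- W; Wm[i] <- W[i] - eps
      num <- (lossWith(ck$set(model$params, Wp)) -
              lossWith(ck$set(model$params, Wm))) / (2 * eps)
      expect_equal(ck$grad[i], num, tolerance = 1e-4)
    }
  }
})

test_that("training is seeded, monotone on a smoke set, and split-safe", {
  cfg <- segnetConfig(inputSize = 16L, nClasses = 3L, channels = c(4L, 6L))
  model <- buildSegNet(cfg, seed = 2, classIds = c(0L, 1L, 27L))
  set.seed(9)
  mkSample <- function(scan) {
    y <- matrix(1L, 16, 16)
    y[5:12, 5:12] <- 2L
    x <- array(0, c(16, 16, 3))
    x[, , 1] <- (y == 2) * 0.8 + runif(256) * 0.1
    list(x = x, y = y, scan = scan, split = "train")
  }
  samples <- lapply(c("s1", "s1", "s2", "s2"), mkSample)

  # epochs = 0 returns the initial weights untouched
  fit0 <- trainSegNet(model, samples, trainConfig(epochs = 0L))
  expect_identical(fit0$model$params, model$params)

  fitA <- trainSegNet(model, samples, trainConfig(epochs = 8L,
                                                  learningRate = 1e-3,
                                                  seed = 5))
  fitB <- trainSegNet(model, samples, trainConfig(epochs = 8L,
                                                  learningRate = 1e-3,
                                                  seed = 5))
  expect_identical(fitA$history, fitB$history)       # deterministic rerun
  expect_lt(tail(fitA$history$trainLoss, 1), fitA$history$trainLoss[1])

  # a scan straddling two splits is an error
  bad <- samples
  bad[[2]]$split <- "val"
  expect_error(trainSegNet(model, bad, trainConfig(epochs = 1L)),
               "more than one split")
})

test_that("prediction is deterministic, size-checked, and palette-valued", {
  cfg <- segnetConfig(inputSize = 16L, nClasses = 3L, channels = c(4L, 6L))
  model <- buildSegNet(cfg, seed = 4, classIds = c(0L, 3L, 27L))
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  p1 <- predictSegNet(model, x)
  p2 <- predictSegNet(model, x)
  expect_identical(p1$classes, p2$classes)
  expect_true(all(p1$classes %in% c(0L, 3L, 27L)))
  expect_no_error(decodeLabelImage(p1$image, scheme))
  expect_error(predictSegNet(model, array(0, c(8, 8, 3))), "match")
})

test_that("scan-level splits never mix a scan across splits", {
  man <- data.frame(mesh = rep(sprintf("s%02d", 1:10), each = 4))
  sp <- splitByScan(man, c(0.8, 0.1, 0.1), seed = 3)
  tab <- unique(sp[, c("mesh", "split")])
  expect_false(anyDuplicated(tab$mesh) > 0)
  expect_setequal(unique(sp$split), c("train", "val", "test"))
})
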