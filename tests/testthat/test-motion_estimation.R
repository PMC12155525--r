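test_that("frame from canonical landmarks is the identity frame", {
  lm <- list(
    molar_cusp_left = c(-10, 12, 0),
    molar_cusp_right = c(-10, -12, 0),
    incisor_edge = c(15, 0, 0),
    incisive_papilla = c(12, 0, -2),
    raphae_mid = c(6, 0, -3),
    raphae_posterior = c(0, 0, -3)
  )
  fr <- buildFrame(lm)
  expect_equal(unname(frameAxes(fr)), diag(3), tolerance = 1e-9)
  expect_equal(frameOrigin(fr), c(12, 0, 0))
})

test_that("frame axes are always right-handed orthonormal and z is occlusal-normal", {
  arch <- smallArch()
  fr <- buildFrame(arch$landmarks)
  A <- frameAxes(fr)
  expect_equal(unname(A %*% t(A)), diag(3), tolerance = 1e-9)
  expect_equal(det(A), 1, tolerance = 1e-9)
  occ <- with(arch$landmarks,
              rbind(molar_cusp_left, molar_cusp_right, incisor_edge))
  for (i in 1:2) {
    expect_equal(sum(A["z", ] * (occ[i + 1, ] - occ[1, ])), 0,
                 tolerance = 1e-9)
  }
})

test_that("degenerate landmark configurations error", {
  lm <- list(molar_cusp_left = c(0, 0, 0), molar_cusp_right = c(1, 0, 0),
             incisor_edge = c(2, 0, 0), incisive_papilla = c(1, 0, -1),
             raphae_mid = c(0.5, 0, -1), raphae_posterior = c(0, 0, -1))
  expect_error(buildFrame(lm), "collinear")
})

test_that("icp recovers a known rigid transform on clean clouds", {
  set.seed(3)
  src <- matrix(runif(300, -10, 10), ncol = 3)
  expect_equal(transformMatrix(icp(src, src)$transform), diag(4),
               tolerance = 1e-9)

  R <- transformMatrix(composeTransform(motionParameters(alpha = 10)))[1:3, 1:3]
  tgt <- t(R %*% t(src)) + rep(c(1, 2, 3), each = nrow(src))
  fit <- icp(src, tgt)
  expect_lt(max(abs(fit$transform@H[1:3, 1:3] - R)), 1e-6)
  expect_lt(max(abs(fit$transform@H[1:3, 4] - c(1, 2, 3))), 1e-6)
  expect_lt(fit$rms, 1e-8)

  expect_error(icp(src[1:2, ], tgt), "3 points")
  expect_error(icp(cbind(1:9, 1:9, 1:9), tgt), "collinear")
})

test_that("icp residual is non-increasing over restarts and iterations", {
  set.seed(4)
  src <- matrix(runif(240, -8, 8), ncol = 3)
  R <- randomRotation()
  tgt <- t(R %*% t(src)) + 0.5
  rms <- vapply(c(1, 3, 10, 50), function(k) icp(src, tgt, maxIter = k)$rms, 0)
  expect_true(all(diff(rms) <= 1e-12))
})

test_that("no-motion scans give all-zero tooth motions", {
  arch <- smallArch()
  rep0 <- estimateToothMotions(arch$mesh, arch$mesh,
                               arch$landmarks, arch$landmarks)
  tab <- motionTable(rep0)
  expect_gt(nrow(tab), 0)
  expect_lt(max(abs(as.matrix(tab[, c("alpha", "beta", "gamma",
                                      "tx", "ty", "tz")]))), 1e-6)
  expect_lt(rep0@stage1Rms, 1e-9)
})

test_that("known per-tooth motions are recovered through the full pipeline", {
  ex <- motionVerificationExperiment(seed = 3, nTeeth = 6,
                                     meshResolution = 1500)
  expect_equal(ex$nFullyRecovered, ex$nTeeth)
  expect_lt(max(ex$table$rotErrDeg), 0.1)
  expect_lt(max(ex$table$transErrMm), 0.01)
})

test_that("motion parameters are invariant to a common rigid motion of both scans", {
  arch <- smallArch()
  ids <- setdiff(sort(unique(meshLabels(arch$mesh))),
                 c(voidLabel(scheme), rugaeLabel(scheme)))
  nm <- labelName(scheme, ids[2])
  mot <- setNames(list(rigidFrom(
    transformMatrix(composeTransform(motionParameters(alpha = 5, gamma = 3)))[1:3, 1:3],
    c(0.5, -0.2, 0.1))), nm)
  post <- applyToothMotion(arch$mesh, mot)

  set.seed(11)
  S <- randomRotation()
  tS <- c(4, -7, 2)
  moveMesh <- function(m) {
    m@vertices <- t(S %*% t(m@vertices)) + rep(tS, each = nrow(m@vertices))
    m
  }
  moveLm <- function(lm) lapply(lm, function(p) as.vector(S %*% p + tS))

  r1 <- estimateToothMotions(arch$mesh, post, arch$landmarks, arch$landmarks)
  r2 <- estimateToothMotions(moveMesh(arch$mesh), moveMesh(post),
                             moveLm(arch$landmarks), moveLm(arch$landmarks))
  t1 <- motionTable(r1); t2 <- motionTable(r2)
  cols <- c("alpha", "beta", "gamma", "tx", "ty", "tz")
  expect_equal(as.matrix(t2[, cols]), as.matrix(t1[, cols]),
               tolerance = 1e-5)
})

test_that("missing rugae or unmatched teeth are handled as specified", {
  arch <- smallArch()
  m <- arch$mesh
  noRugae <- m
  noRugae@label[noRugae@label == rugaeLabel(scheme)] <- voidLabel(scheme)
  expect_error(estimateToothMotions(noRugae, m), "rugae")
  expect_error(estimateToothMotions(m, noRugae), "rugae")

  ids <- setdiff(sort(unique(meshLabels(m))), c(voidLabel(scheme), rugaeLabel(scheme)))
  post <- m
  post@label[post@label == ids[1]] <- voidLabel(scheme)
  r <- estimateToothMotions(m, post, arch$landmarks, arch$landmarks)
  expect_true(ids[1] %in% r@unmatched)
  expect_false(labelName(scheme, ids[1]) %in% motionTable(r)$name)
})
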