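test_that("vote accumulation and finalization follow majority with fixed ties", {
  n <- 4L
  obs <- list(c(1L, 2L, NA, 0L), c(1L, 3L, NA, 0L), c(1L, 2L, NA, NA))
  tal <- accumulateVotes(obs, scheme)
  expect_equal(tal$visibility, c(3L, 3L, 0L, 2L))
  expect_equal(unname(tal$votes[2, "2"]), 2L)
  expect_equal(unname(tal$votes[2, "3"]), 1L)
  expect_equal(rowSums(tal$votes), tal$visibility)   # one vote per view

  lab <- finalizeLabels(tal, scheme)
  expect_equal(lab[1], 1L)         # k agreeing views
  expect_equal(lab[2], 2L)         # {2:2, 3:1} -> 2
  expect_equal(lab[3], voidLabel(scheme))   # never visible -> void

  # tie broken by the lowest label id, deterministically
  tie <- accumulateVotes(list(c(5L), c(9L)), scheme)
  expect_equal(finalizeLabels(tie, scheme), 5L)
  expect_equal(finalizeLabels(tie, scheme), 5L)
  # empty view list is rejected
  expect_error(accumulateVotes(list(), scheme), "no observations")
})

test_that("ownership baking closes the loop on ground-truth renders", {
  arch <- smallArch()
  m <- arch$mesh
  bs <- boundingSphere(m)
  poses <- sampleCameraPoses(30, seed = 21, radius = 2.5 * bs$radius,
                             center = bs$center, width = 96L, height = 96L)
  obs <- lapply(poses, function(p) {
    v <- renderView(m, p)
    o <- bakeView(m, p, labelImage(v))
    # every observation is the vertex's own label
    expect_true(all(o[!is.na(o)] == meshLabels(m)[!is.na(o)]))
    o
  })
  tal <- accumulateVotes(obs, scheme)
  lab <- finalizeLabels(tal, scheme)
  vis <- tal$visibility > 0
  expect_gt(mean(vis), 0.8)
  m3 <- metrics3D(lab, meshLabels(m), scheme, subset = vis)
  expect_equal(m3$meanIoU, 1)
})

test_that("adding a ground-truth view never lowers any class IoU", {
  arch <- smallArch()
  m <- arch$mesh
  bs <- boundingSphere(m)
  poses <- sampleCameraPoses(6, seed = 31, radius = 2.5 * bs$radius,
                             center = bs$center, width = 64L, height = 64L)
  obs <- lapply(poses, function(p) bakeView(m, p, labelImage(renderView(m, p))))
  iouAfter <- function(k) {
    tal <- accumulateVotes(obs[seq_len(k)], scheme)
    m3 <- metrics3D(finalizeLabels(tal, scheme), meshLabels(m), scheme,
                    subset = tal$visibility > 0)
    m3$perClass
  }
  prev <- iouAfter(3)
  for (k in 4:6) {
    cur <- iouAfter(k)
    both <- !is.na(prev) & !is.na(cur)
    expect_true(all(cur[both] >= prev[both] - 1e-12))
    prev <- cur
  }
})

test_that("depth-test baking respects occlusion and image bounds", {
  # a 6x6 vertex grid plane at z = 0: interior vertices project inside
  # their covering faces, so they cast depth-test observations
  g <- seq(-10, 10, length.out = 6)
  verts <- cbind(rep(g, 6), rep(g, each = 6), 0)
  idx <- function(i, j) (j - 1L) * 6L + i
  faces <- do.call(rbind, lapply(1:5, function(j) do.call(rbind, lapply(1:5,
    function(i) rbind(c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                      c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))))))
  plane <- LabeledMesh(verts, faces, color = matrix(200, 36, 3),
                       label = rep(3L, 36), scheme = scheme)
  pose <- topDownPose()
  vP <- renderView(plane, pose)

  # unoccluded: visible vertices observe their own label
  obs <- bakeView(plane, pose, labelImage(vP), depthBuffer(vP),
                  method = "depth")
  expect_true(any(!is.na(obs)))
  expect_true(all(obs[!is.na(obs)] == 3L))

  # the same plane under an occluding quad at z = 5 observes nothing
  both <- LabeledMesh(
    rbind(verts, c(-30, -30, 5), c(30, -30, 5), c(30, 30, 5), c(-30, 30, 5)),
    rbind(faces, c(37L, 38L, 39L), c(37L, 39L, 40L)),
    color = matrix(128, 40, 3),
    label = c(rep(3L, 36), rep(rugaeLabel(scheme), 4)), scheme = scheme)
  vBoth <- renderView(both, pose)
  obs2 <- bakeView(both, pose, labelImage(vBoth), depthBuffer(vBoth),
                   method = "depth")
  expect_true(all(is.na(obs2[1:36])))         # behind the occluder

  # vertices projecting outside the image observe nothing
  far <- plane
  far@vertices <- far@vertices + rep(c(1000, 0, 0), each = 36)
  obs3 <- bakeView(far, pose, labelImage(vP), depthBuffer(vP),
                   method = "depth")
  expect_true(all(is.na(obs3)))

  expect_error(bakeView(plane, pose, labelImage(vP)[1:10, 1:10, ],
                        depthBuffer(vP), method = "depth"), "size")
})

test_that("baking is deterministic on identical inputs", {
  arch <- smallArch()
  m <- arch$mesh
  bs <- boundingSphere(m)
  p <- sampleCameraPoses(1, seed = 8, radius = 2.5 * bs$radius,
                         center = bs$center, width = 64L, height = 64L)[[1]]
  v <- renderView(m, p)
  expect_identical(bakeView(m, p, labelImage(v)), bakeView(m, p, labelImage(v)))
})

test_that("segmentation into components partitions the non-void mesh", {
  m <- smallArch()$mesh
  subs <- segmentComponents(m)
  present <- setdiff(sort(unique(meshLabels(m))), voidLabel(scheme))
  expect_length(subs, length(present))
  total <- sum(vapply(subs, function(s) nrow(meshVertices(s)), 0L))
  expect_equal(total, sum(meshLabels(m) != voidLabel(scheme)))
  # single-label content per submesh
  for (s in subs) expect_length(unique(meshLabels(s)), 1L)
  # faces are valid in every submesh
  for (s in subs) expect_true(validObject(s))
})
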