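test_that("pose sampling respects elevation, orientation, and seeding", {
  poses <- sampleCameraPoses(100, seed = 1, radius = 50)
  expect_length(poses, 100L)
  for (p in poses[1:10]) {
    expect_gt(p@position[3], 0)            # above the occlusal plane
    f <- p@lookAt - p@position
    expect_gt(sum(f * (p@lookAt - p@position)), 0)
  }
  el <- vapply(poses, function(p) asin(p@position[3] / 50) * 180 / pi, 0)
  expect_true(all(el >= 15 - 1e-9))
  p2 <- sampleCameraPoses(100, seed = 1, radius = 50)
  expect_identical(
    vapply(poses, function(p) p@position, numeric(3)),
    vapply(p2, function(p) p@position, numeric(3)))
  expect_error(sampleCameraPoses(0), ">= 1")
})

test_that("pose elevation matches the uniform-solid-angle expectation", {
  n <- 10000L
  poses <- sampleCameraPoses(n, seed = 12, radius = 1, minElevation = 15)
  z <- vapply(poses, function(p) p@position[3], 0)
  # z = sin(elevation) is uniform on [sin(15 deg), 1]
  s0 <- sin(15 * pi / 180)
  expect_lt(abs(mean(z) - (1 + s0) / 2), 3 * sqrt(1 / 12) * (1 - s0) / sqrt(n))
  expect_gt(min(z), s0 - 1e-12)
})

test_that("pinhole projection lands vertices at hand-computed pixels", {
  # camera on the -x axis looking along +x: the basis is right = (0,-1,0),
  # down = (0,0,-1), forward = (1,0,0), so camera coordinates of a world
  # point p are X = -p_y, Y = -p_z, Z = 50 + p_x, and pixels follow
  # (f X / Z + cx, f Y / Z + cy)
  pose <- cameraPose(position = c(-50, 0, 0), lookAt = c(0, 0, 0),
                     focal = 100, width = 64L, height = 64L)
  pts <- rbind(c(0, 0, 0), c(0, -5, 0), c(10, 0, -6))
  pr <- projectPoints(pose, pts)
  expect_equal(pr$z, c(50, 50, 60))
  expect_equal(pr$px, 32 + 100 * c(0, 5, 0) / pr$z)
  expect_equal(pr$py, 32 + 100 * c(0, 0, 6) / pr$z)
})

test_that("rasterization covers a triangle identically in texture and label", {
  m <- triangleMesh(label = 5L)
  v <- renderView(m, topDownPose(), lightingConfig("glow"))
  covered <- pixelFaceMap(v) > 0
  expect_gt(sum(covered), 50)
  expect_true(all(is.finite(depthBuffer(v)) == covered))
  labCovered <- apply(labelImage(v), c(1, 2), function(px) any(px > 0))
  expect_identical(unname(labCovered), unname(covered))
  # single label mesh: all covered pixels one palette color
  ids <- unique(as.vector(decodeLabelImage(labelImage(v), scheme)))
  expect_setequal(ids, c(5L, voidLabel(scheme)))
})

test_that("glow shading reproduces vertex colors exactly at vertices", {
  # one vertex at the image center, axis-aligned triangle, known color
  m <- LabeledMesh(rbind(c(0, 0, 0), c(10, 0, 0), c(0, -10, 0)),
                   rbind(c(1L, 2L, 3L)),
                   color = matrix(rep(c(120, 80, 40), each = 3), 3, 3),
                   label = rep(1L, 3), scheme = scheme)
  v <- renderView(m, topDownPose(), lightingConfig("glow"))
  ctr <- which(pixelFaceMap(v) > 0, arr.ind = TRUE)[1, ]
  px <- v@texture[ctr[1], ctr[2], ]
  expect_equal(px * 255, c(120, 80, 40), tolerance = 1e-9)
})

test_that("empty meshes render to background only", {
  m <- LabeledMesh(matrix(numeric(), 0, 3), matrix(integer(), 0, 3),
                   color = matrix(numeric(), 0, 3), label = integer())
  v <- renderView(m, topDownPose())
  expect_true(all(pixelFaceMap(v) == 0))
  expect_true(all(v@texture == 0))
})

test_that("an occluding surface removes hidden pixels from both images", {
  # labeled triangle at z = 0, occluding quad above it at z = 5
  tri <- triangleMesh(label = 3L, z = 0)
  quad <- LabeledMesh(
    rbind(c(-20, -20, 5), c(20, -20, 5), c(20, 20, 5), c(-20, 20, 5),
          tri@vertices),
    rbind(c(1L, 2L, 3L), c(1L, 3L, 4L), c(5L, 6L, 7L)),
    color = matrix(128, 7, 3),
    label = c(rep(rugaeLabel(scheme), 4), rep(3L, 3)), scheme = scheme)
  vTri <- renderView(tri, topDownPose())
  vBoth <- renderView(quad, topDownPose())
  idsBoth <- decodeLabelImage(labelImage(vBoth), scheme)
  expect_false(any(idsBoth == 3L))            # fully occluded
  expect_lt(max(abs(depthBuffer(vBoth)[is.finite(depthBuffer(vBoth))] - 45)), 1e-9)
})

test_that("label images contain only palette colors under all lighting modes", {
  m <- smallArch()$mesh
  bs <- boundingSphere(m)
  pose <- sampleCameraPoses(1, seed = 4, radius = 2.5 * bs$radius,
                            center = bs$center, width = 96L, height = 96L)[[1]]
  for (mode in c("glow", "ambient", "spot")) {
    v <- renderView(m, pose, lightingConfig(mode))
    expect_no_error(decodeLabelImage(labelImage(v), scheme))
    expect_true(all(v@texture >= 0 & v@texture <= 1))
  }
})

test_that("dataset generation writes n x v pairs with a reproducible manifest", {
  meshes <- list(a = smallArch()$mesh,
                 b = generateArch(archParams(nTeeth = 2, meshResolution = 900,
                                             seed = 3))$mesh)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generateDataset(meshes, 3, d1, seed = 9, width = 48L, height = 48L)
  m2 <- generateDataset(meshes, 3, d2, seed = 9, width = 48L, height = 48L)
  expect_equal(nrow(m1), 6L)
  expect_length(list.files(d1, pattern = "png$"), 12L)
  # manifests identical up to output paths
  drop <- c("texture", "label")
  expect_identical(m1[, setdiff(names(m1), drop)],
                   m2[, setdiff(names(m2), drop)])
  # poses reconstruct exactly
  p <- poseFromManifestRow(m1[4, ])
  expect_s4_class(p, "CameraPose")
  expect_equal(p@focal, m1$focal[4])
})

test_that("label pixel statistics count pixels and vertices per label", {
  m <- triangleMesh(label = 7L)
  d <- withr::local_tempdir()
  man <- generateDataset(list(t = m), 1, d, seed = 2, width = 32L,
                         height = 32L, lightingModes = "glow",
                         fovJitter = 0)
  st <- labelPixelStats(man, list(t = m))
  row <- st$table[st$table$id == 7L, ]
  img <- decodeLabelImage(png::readPNG(man$label[1]), scheme)
  expect_equal(row$pixels, sum(img == 7L))
  expect_equal(row$vertices, 3)
  expect_equal(row$ratio, sum(img == 7L) / 3)
  # absent labels have zero counts and are excluded from the summary
  absent <- st$table[st$table$id == 1L, ]
  expect_equal(absent$pixels, 0)
  expect_false(absent$included)
  # doubling the views doubles pixel counts, not vertex counts
  man2 <- rbind(man, man)
  st2 <- labelPixelStats(man2, list(t = m))
  expect_equal(st2$table$pixels[st2$table$id == 7L], 2 * row$pixels)
  expect_equal(st2$table$ratio[st2$table$id == 7L], 2 * row$ratio)
})
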