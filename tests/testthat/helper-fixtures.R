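# shared fixtures, built in code at test time

scheme <- defaultLabelScheme()

# small labeled arch used across tests (memoised per session)
smallArch <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generateArch(archParams(nTeeth = 6, meshResolution = 1500,
                                        seed = 101), scheme)
    }
    cache
  }
})

# a single triangle mesh with one label
triangleMesh <- function(label = 1L, z = 10) {
  LabeledMesh(
    vertices = rbind(c(-5, -5, z), c(5, -5, z), c(0, 5, z)),
    faces = rbind(c(1L, 2L, 3L)),
    color = rbind(c(255, 0, 0), c(0, 255, 0), c(0, 0, 255)),
    label = rep(label, 3), scheme = scheme
  )
}

# camera looking straight down the -z axis from above the origin
topDownPose <- function(d = 50, focal = 100, size = 64L) {
  cameraPose(position = c(0, 0, d), lookAt = c(0, 0, 0),
             focal = focal, width = size, height = size)
}

# random proper rotation (Haar via QR sign fix)
randomRotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rigidFrom <- function(R, t) {
  H <- diag(4)
  H[1:3, 1:3] <- R
  H[1:3, 4] <- t
  rigidTransform(H)
}
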