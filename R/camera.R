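#' Construct a camera pose
#'
#' @param position,lookAt length-3 points (mm).
#' @param roll rotation about the optical axis (radians).
#' @param focal focal length in pixels.
#' @param width,height image size in pixels.
#' @param center principal point; defaults to the image center.
#' @return a [CameraPose-class].
#' @export
cameraPose <- function(position, lookAt, roll = 0, focal = 220,
                       width = 256L, height = 256L, center = NULL) {
  if (is.null(center)) center <- c(width / 2, height / 2)
  new("CameraPose", position = as.numeric(position),
      lookAt = as.numeric(lookAt), roll = as.numeric(roll),
      focal = as.numeric(focal), center = as.numeric(center),
      width = as.integer(width), height = as.integer(height))
}

setMethod("show", "CameraPose", function(object) {
  cat(sprintf("CameraPose: %dx%d, f=%.1f px, position (%s)\n",
              object@width, object@height, object@focal,
              paste(sprintf("%.2f", object@position), collapse = ", ")))
})

# orthonormal camera basis: rows right, down, forward (view matrix rotation)
.cameraBasis <- function(pose) {
  f <- .unit(pose@lookAt - pose@position)
  zref <- if (abs(f[3]) > 0.995) c(1, 0, 0) else c(0, 0, 1)
  r <- .unit(.cross3(f, zref))
  u <- .cross3(r, f)
  cr <- cos(pose@roll); sr <- sin(pose@roll)
  r2 <- cr * r + sr * u
  u2 <- -sr * r + cr * u
  rbind(right = r2, down = -u2, forward = f)
}

#' Project points through a camera
#'
#' Pinhole projection: camera coordinates (X right, Y down, Z forward),
#' pixel coordinates \code{(f X / Z + cx, f Y / Z + cy)}.
#' @param pose a [CameraPose-class].
#' @param points numeric N x 3 world points.
#' @return list with \code{px}, \code{py} (pixels) and \code{z}
#'   (camera-space depth, mm).
#' @export
projectPoints <- function(pose, points) {
  B <- .cameraBasis(pose)
  pc <- t(B %*% (t(points) - pose@position))
  z <- pc[, 3]
  list(px = pose@focal * pc[, 1] / z + pose@center[1],
       py = pose@focal * pc[, 2] / z + pose@center[2],
       z = z)
}

#' Sample random camera poses on the upper hemisphere
#'
#' Poses are uniform in solid angle on the hemisphere of the given radius
#' above the minimum elevation, with the optical axis pointing at
#' \code{center} and the camera rolled uniformly about its optical axis.
#' The elevation, azimuth and roll ranges can be restricted for
#' constrained-view protocols; the defaults reproduce the full randomized
#' hemisphere. \code{fovJitter} draws a per-pose multiplicative focal
#' factor in \code{[1 - fovJitter, 1 + fovJitter]}, randomizing the
#' perspective distortion.
#'
#' @param n number of poses (>= 1).
#' @param seed RNG seed.
#' @param radius hemisphere radius (mm).
#' @param center length-3 hemisphere center (mm).
#' @param width,height image size (pixels).
#' @param focal nominal focal length in pixels; default 0.85 * width keeps
#'   a scan at 2.5 bounding radii comfortably in frame.
#' @param minElevation minimum camera elevation (degrees).
#' @param elevationRange optional length-2 elevation interval (degrees)
#'   overriding \code{c(minElevation, 90)}.
#' @param azimuthRange azimuth interval (degrees), default full circle.
#' @param rollRange roll interval (degrees), default full circle.
#' @param fovJitter perspective-distortion factor amplitude in [0, 1).
#' @return list of [CameraPose-class].
#' @export
sampleCameraPoses <- function(n, seed = 1L, radius = 120, center = c(0, 0, 0),
                              width = 256L, height = 256L, focal = NULL,
                              minElevation = 15, elevationRange = NULL,
                              azimuthRange = c(0, 360),
                              rollRange = c(0, 360), fovJitter = 0) {
  if (n < 1) stop("n must be >= 1")
  if (is.null(focal)) focal <- 0.85 * width
  if (is.null(elevationRange)) elevationRange <- c(minElevation, 90)
  .withSeed(seed, {
    s <- sin(elevationRange * pi / 180)
    sinel <- stats::runif(n, s[1], s[2])      # uniform in solid angle
    el <- asin(sinel)
    az <- stats::runif(n, azimuthRange[1], azimuthRange[2]) * pi / 180
    roll <- stats::runif(n, rollRange[1], rollRange[2]) * pi / 180
    fj <- if (fovJitter > 0) stats::runif(n, 1 - fovJitter, 1 + fovJitter)
          else rep(1, n)
    lapply(seq_len(n), function(i) {
      dir <- c(cos(el[i]) * cos(az[i]), cos(el[i]) * sin(az[i]), sinel[i])
      cameraPose(position = center + radius * dir, lookAt = center,
                 roll = roll[i], focal = focal * fj[i],
                 width = width, height = height)
    })
  })
}
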