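.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate direction (zero length)")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Anatomical coordinate frame from the six landmark spheres
#'
#' The occlusal plane passes through the two molar cusps and the incisor
#' edge; the sagittal plane contains the least-squares line through the
#' three median-raphae points and the occlusal normal. The frame has its
#' z-axis normal to the occlusal plane (oriented away from the palate
#' vault), its x-axis along the intersection of the occlusal and sagittal
#' planes (oriented anteriorly, toward the incisor edge), y completing a
#' right-handed set, and its origin at the normal projection of the
#' incisive papilla onto the occlusal plane.
#'
#' @param landmarks named list of length-3 points (mm) with entries
#'   \code{molar_cusp_left}, \code{molar_cusp_right}, \code{incisor_edge},
#'   \code{incisive_papilla}, and at least two further \code{raphae_*}
#'   points along the median raphae.
#' @return a [CoordinateFrame-class].
#' @export
buildFrame <- function(landmarks) {
  need <- c("molar_cusp_left", "molar_cusp_right", "incisor_edge",
            "incisive_papilla")
  if (!all(need %in% names(landmarks))) {
    stop("landmarks must include ", paste(need, collapse = ", "))
  }
  p1 <- landmarks$molar_cusp_left
  p2 <- landmarks$molar_cusp_right
  p3 <- landmarks$incisor_edge
  raphae <- c(list(landmarks$incisive_papilla),
              landmarks[grepl("^raphae", names(landmarks))])
  if (length(raphae) < 3L) stop("need at least 3 median-raphae points")
  R <- do.call(rbind, raphae)

  n <- .cross3(p2 - p1, p3 - p1)
  if (sqrt(sum(n^2)) < 1e-9 * max(1, sum(abs(p2 - p1)))) {
    stop("occlusal landmarks are collinear; occlusal plane is degenerate")
  }
  z <- .unit(n)
  # orient z away from the palate vault (raphae lie palatal to the cusps)
  if (sum(z * (colMeans(rbind(p1, p2, p3)) - colMeans(R))) < 0) z <- -z

  # least-squares direction of the raphae line
  Rc <- sweep(R, 2, colMeans(R))
  sv <- svd(Rc)
  if (sv$d[1] < 1e-9) stop("raphae points are coincident")
  d <- sv$v[, 1]
  x <- d - sum(d * z) * z           # intersection of occlusal and sagittal
  if (sqrt(sum(x^2)) < 1e-9) {
    stop("raphae line is normal to the occlusal plane; frame is degenerate")
  }
  x <- .unit(x)
  if (sum(x * (p3 - colMeans(R))) < 0) x <- -x   # anterior orientation
  y <- .cross3(z, x)

  papilla <- landmarks$incisive_papilla
  origin <- papilla - sum((papilla - p1) * z) * z
  new("CoordinateFrame", origin = origin, axes = rbind(x = x, y = y, z = z))
}

#' @describeIn CoordinateFrame-class frame origin (mm).
#' @param frame a [CoordinateFrame-class].
#' @export
frameOrigin <- function(frame) frame@origin

#' @describeIn CoordinateFrame-class 3 x 3 axes matrix (rows x, y, z).
#' @export
frameAxes <- function(frame) frame@axes

setMethod("show", "CoordinateFrame", function(object) {
  cat("CoordinateFrame: origin (",
      paste(sprintf("%.3f", object@origin), collapse = ", "), ") mm\n")
})

#' World-to-frame rigid transform
#'
#' Returns the [RigidTransform-class] taking world coordinates to frame
#' (local anatomical) coordinates: \code{l = A (p - o)}.
#' @param frame a [CoordinateFrame-class].
#' @export
worldToFrame <- function(frame) {
  H <- diag(4)
  H[1:3, 1:3] <- frame@axes
  H[1:3, 4] <- -frame@axes %*% frame@origin
  rigidTransform(H)
}

#' Rigid transform aligning one frame onto another
#'
#' Returns the transform mapping points expressed in the world of
#' \code{from} so that \code{from}'s anatomical frame coincides with
#' \code{to}'s: \code{H = toFrame^-1 . fromFrame} in world-to-local terms.
#' Used as the rough stage-0 initialization of motion estimation.
#' @param from,to [CoordinateFrame-class] objects.
#' @export
frameAlignment <- function(from, to) {
  A <- worldToFrame(from)@H
  B <- worldToFrame(to)@H
  rigidTransform(solve(B) %*% A)
}
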