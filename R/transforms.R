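# Rigid transforms and their Euler decomposition.
#
# Convention (fixed once, used everywhere): a rigid motion is composed as
#   H = Tz Ty Tx Rz(alpha) Ry(beta) Rx(gamma)
# where the y-rotation is counter-clockwise about the right-handed y axis
# and the x- and z-rotations are measured clockwise (i.e. Rx(g) and Rz(a)
# are the transposes of the usual right-handed matrices). Under this
# convention the inverse kinematics are exactly
#   beta  = -asin(R31)
#   gamma = -atan2(R32, R33)
#   alpha = -atan2(R21, R11)
# and decomposeTransform() is the exact inverse of composeTransform().
# Two-argument arctangents keep quadrants unambiguous.

#' Tooth motion parameters
#'
#' Three rotations (degrees) and three translations (mm) describing one
#' rigid motion: \code{alpha} about z, \code{beta} about y, \code{gamma}
#' about x. \code{gimbal} flags the singular decomposition branch
#' (|beta| = 90 degrees), where gamma is fixed at 0 and the residual
#' rotation folded into alpha.
#'
#' @slot alpha,beta,gamma rotation angles in degrees.
#' @slot tx,ty,tz translations in mm.
#' @slot gimbal logical, TRUE when decomposition hit the singular branch.
#' @export
setClass("MotionParameters", representation(
  alpha = "numeric", beta = "numeric", gamma = "numeric",
  tx = "numeric", ty = "numeric", tz = "numeric", gimbal = "logical"
))

#' @describeIn MotionParameters-class constructor; angles in degrees,
#'   translations in mm.
#' @param alpha,beta,gamma rotations about z, y, x (degrees).
#' @param tx,ty,tz translations (mm).
#' @param gimbal singular-branch flag.
#' @export
motionParameters <- function(alpha = 0, beta = 0, gamma = 0,
                             tx = 0, ty = 0, tz = 0, gimbal = FALSE) {
  new("MotionParameters", alpha = alpha, beta = beta, gamma = gamma,
      tx = tx, ty = ty, tz = tz, gimbal = gimbal)
}

setMethod("show", "MotionParameters", function(object) {
  cat(sprintf(
    "MotionParameters: alpha=%.4f beta=%.4f gamma=%.4f deg, T=(%.4f, %.4f, %.4f) mm%s\n",
    object@alpha, object@beta, object@gamma,
    object@tx, object@ty, object@tz,
    if (object@gimbal) " [gimbal]" else ""))
})

#' @describeIn MotionParameters-class coerce to a named numeric vector.
#' @param params a \code{MotionParameters}.
#' @export
motionAsVector <- function(params) {
  c(alpha = params@alpha, beta = params@beta, gamma = params@gamma,
    tx = params@tx, ty = params@ty, tz = params@tz)
}

#' Construct a RigidTransform from a 4 x 4 matrix
#' @param H numeric 4 x 4 homogeneous matrix.
#' @export
rigidTransform <- function(H) new("RigidTransform", H = H)

#' @describeIn RigidTransform-class the 4 x 4 homogeneous matrix.
#' @param transform a [RigidTransform-class].
#' @export
transformMatrix <- function(transform) transform@H

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform (4 x 4 homogeneous):\n")
  print(round(object@H, 6))
})

#' The identity rigid transform
#' @export
identityTransform <- function() rigidTransform(diag(4))

#' Apply a rigid transform to points
#' @param transform a [RigidTransform-class] or 4 x 4 matrix.
#' @param points numeric N x 3 matrix.
#' @return transformed N x 3 matrix.
#' @export
transformPoints <- function(transform, points) {
  H <- if (is(transform, "RigidTransform")) transform@H else transform
  pts <- as.matrix(points)
  t(H[1:3, 1:3] %*% t(pts) + H[1:3, 4])
}

# axis rotation blocks under the package convention (angles in radians)
.rotX <- function(g) {
  c <- cos(g); s <- sin(g)
  matrix(c(1, 0, 0, 0, c, -s, 0, s, c), 3, 3)      # clockwise about x
}
.rotY <- function(b) {
  c <- cos(b); s <- sin(b)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)      # counter-clockwise about y
}
.rotZ <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, -s, 0, s, c, 0, 0, 0, 1), 3, 3)      # clockwise about z
}

#' Compose a rigid transform from motion parameters
#'
#' Builds \code{H = Tz Ty Tx Rz(alpha) Ry(beta) Rx(gamma)} under the
#' package's fixed axis-rotation sign convention (see
#' \code{R/transforms.R} header comment): translations commute, so the
#' rotation block is \code{Rz Ry Rx} and the translation column is
#' \code{(tx, ty, tz)}.
#'
#' @param params a [MotionParameters-class], or a named numeric vector with
#'   elements \code{alpha, beta, gamma, tx, ty, tz} (degrees / mm).
#' @return a [RigidTransform-class].
#' @export
composeTransform <- function(params) {
  if (is(params, "MotionParameters")) params <- motionAsVector(params)
  d2r <- pi / 180
  R <- .rotZ(params[["alpha"]] * d2r) %*%
       .rotY(params[["beta"]] * d2r) %*%
       .rotX(params[["gamma"]] * d2r)
  H <- diag(4)
  H[1:3, 1:3] <- R
  H[1:3, 4] <- c(params[["tx"]], params[["ty"]], params[["tz"]])
  rigidTransform(H)
}

#' Decompose a rigid transform into motion parameters
#'
#' Inverse kinematics of [composeTransform()]: \code{beta = -asin(R31)}
#' (the |beta| <= 90 degree branch; larger rotations are clinically
#' implausible for tooth movement and the second solution is excluded),
#' \code{gamma = -atan2(R32, R33)}, \code{alpha = -atan2(R21, R11)},
#' translations read from the fourth column. At gimbal lock
#' (|R31| = 1, i.e. beta = +/-90 degrees) only alpha -/+ gamma is
#' determined; gamma is set to 0, the full residual rotation folded into
#' alpha, and the \code{gimbal} flag set. In every case
#' \code{composeTransform(decomposeTransform(H))} reproduces \code{H}.
#'
#' @param transform a [RigidTransform-class] or 4 x 4 matrix.
#' @param tol threshold on \code{1 - |R31|} below which the singular
#'   branch is taken.
#' @return a [MotionParameters-class] (degrees, mm).
#' @export
decomposeTransform <- function(transform, tol = 1e-9) {
  H <- if (is(transform, "RigidTransform")) transform@H else transform
  R <- H[1:3, 1:3]
  r2d <- 180 / pi
  tx <- H[1, 4]; ty <- H[2, 4]; tz <- H[3, 4]
  s <- max(-1, min(1, R[3, 1]))
  if (1 - abs(s) < tol) {
    # beta = +/-90: R21 = R11 = 0; recover alpha from the first row
    beta <- if (s < 0) 90 else -90
    gamma <- 0
    alpha <- if (s < 0) atan2(R[1, 2], R[1, 3]) * r2d
             else       atan2(R[1, 2], -R[1, 3]) * r2d
    return(motionParameters(alpha, beta, gamma, tx, ty, tz, gimbal = TRUE))
  }
  beta <- -asin(s) * r2d
  gamma <- -atan2(R[3, 2], R[3, 3]) * r2d
  alpha <- -atan2(R[2, 1], R[1, 1]) * r2d
  motionParameters(alpha, beta, gamma, tx, ty, tz, gimbal = FALSE)
}

#' Rotation angle (degrees) between two rigid transforms
#'
#' The geodesic angle of \code{R1 R2'}; 0 iff the rotation blocks agree.
#' @param a,b [RigidTransform-class] objects or 4 x 4 matrices.
#' @export
rotationAngleBetween <- function(a, b) {
  Ha <- if (is(a, "RigidTransform")) a@H else a
  Hb <- if (is(b, "RigidTransform")) b@H else b
  Rrel <- Ha[1:3, 1:3] %*% t(Hb[1:3, 1:3])
  cosang <- (sum(diag(Rrel)) - 1) / 2
  acos(max(-1, min(1, cosang))) * 180 / pi
}
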