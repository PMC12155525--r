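# Point-to-point ICP with optional trimming, and the two-stage
# rugae-anchored tooth motion estimator.

.kabsch <- function(P, Q) {
  # least-squares rigid fit Q ~ R P + t (Kabsch/SVD, det-corrected)
  pbar <- colMeans(P); qbar <- colMeans(Q)
  C <- crossprod(sweep(Q, 2, qbar), sweep(P, 2, pbar))  # sum q_c p_c'
  sv <- svd(C)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t <- qbar - R %*% pbar
  H <- diag(4)
  H[1:3, 1:3] <- R
  H[1:3, 4] <- t
  H
}

.checkCloud <- function(pts, what) {
  if (nrow(pts) < 3L) stop(what, " needs at least 3 points")
  sv <- svd(sweep(pts, 2, colMeans(pts)))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    stop(what, " is collinear/degenerate")
  }
  invisible(TRUE)
}

#' Iterative closest point rigid registration
#'
#' Point-to-point ICP: alternate nearest-neighbour correspondences from the
#' transformed source into the target with a det-corrected SVD (Kabsch)
#' rigid fit, until the RMS improvement falls below \code{tol} or
#' \code{maxIter} is reached. With \code{trimFraction > 0} the worst
#' correspondences (largest distances) are dropped from each fit, which
#' robustifies patch-border registration against mucosa deformation.
#'
#' @param source numeric N x 3 matrix, points to move.
#' @param target numeric M x 3 matrix, fixed points.
#' @param maxIter maximum iterations.
#' @param tol convergence threshold on the RMS improvement (mm).
#' @param trimFraction fraction (0 to <1) of worst correspondences dropped.
#' @param init optional [RigidTransform-class] initial guess (source to
#'   target); defaults to identity.
#' @return list with \code{transform} (a [RigidTransform-class] mapping
#'   source to target), \code{rms} (final trimmed RMS distance, mm),
#'   \code{iterations}, and \code{converged}.
#' @export
icp <- function(source, target, maxIter = 100L, tol = 1e-10,
                trimFraction = 0, init = NULL) {
  source <- as.matrix(source); target <- as.matrix(target)
  .checkCloud(source, "source")
  .checkCloud(target, "target")
  if (trimFraction < 0 || trimFraction >= 1) {
    stop("trimFraction must be in [0, 1)")
  }
  H <- if (is.null(init)) diag(4) else init@H
  nKeep <- max(3L, ceiling(nrow(source) * (1 - trimFraction)))
  lastRms <- Inf
  rms <- Inf
  it <- 0L
  converged <- FALSE
  while (it < maxIter) {
    it <- it + 1L
    moved <- transformPoints(H, source)
    nn <- cpp_nearest(moved, target)
    sel <- seq_len(nrow(source))
    if (nKeep < nrow(source)) {
      sel <- order(nn$dist2)[seq_len(nKeep)]
    }
    H <- .kabsch(source[sel, , drop = FALSE],
                 target[nn$index[sel], , drop = FALSE])
    moved <- transformPoints(H, source[sel, , drop = FALSE])
    rms <- sqrt(mean(rowSums((moved - target[nn$index[sel], , drop = FALSE])^2)))
    if (is.finite(lastRms) && abs(lastRms - rms) < tol) {
      converged <- TRUE
      break
    }
    lastRms <- rms
  }
  list(transform = rigidTransform(H), rms = rms,
       iterations = it, converged = converged)
}

# alternative ICP initializations for escaping local minima: principal-axes
# alignment (all four proper sign combinations; exact up to sampling for
# clean clouds) followed by a coarse grid of single-axis rotations about
# the target centroid
.restartInits <- function(q, p, Hinit) {
  inits <- list()
  cq <- colMeans(q); cp <- colMeans(p)
  Uq <- svd(sweep(q, 2, cq))$v
  Up <- svd(sweep(p, 2, cp))$v
  if (det(Uq) < 0) Uq[, 3] <- -Uq[, 3]
  if (det(Up) < 0) Up[, 3] <- -Up[, 3]
  for (s in list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))) {
    R <- Up %*% diag(s) %*% t(Uq)
    H <- diag(4)
    H[1:3, 1:3] <- R
    H[1:3, 4] <- cp - R %*% cq
    inits[[length(inits) + 1L]] <- H
  }
  for (ang in c(10, -10, 20, -20, 30, -30, 45, -45) * pi / 180) {
    for (axis in 1:3) {
      Rp <- diag(3)
      ij <- setdiff(1:3, axis)
      Rp[ij, ij] <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
      H <- diag(4)
      H[1:3, 1:3] <- Rp
      H[1:3, 4] <- cp - Rp %*% cp
      inits[[length(inits) + 1L]] <- H %*% Hinit
    }
  }
  inits
}

#' Per-tooth motion report
#'
#' Result of [estimateToothMotions()]: one row per matched tooth with the
#' decomposed motion parameters (degrees / mm) and ICP residual, the
#' world-frame motion transforms, the stage-1 rugae residual, and the ids
#' of teeth present in only one scan.
#'
#' @slot table data.frame with columns \code{id}, \code{name},
#'   \code{alpha}, \code{beta}, \code{gamma}, \code{tx}, \code{ty},
#'   \code{tz}, \code{rms}, \code{gimbal}.
#' @slot transforms named list of [RigidTransform-class], world-frame
#'   pre-to-post motion per tooth.
#' @slot stage1Rms numeric, rugae ICP residual RMS (mm).
#' @slot unmatched integer ids of teeth present in only one mesh.
#' @export
setClass("ToothMotionReport", representation(
  table = "data.frame", transforms = "list",
  stage1Rms = "numeric", unmatched = "integer"
))

setMethod("show", "ToothMotionReport", function(object) {
  cat("ToothMotionReport:", nrow(object@table), "teeth, stage-1 rugae RMS",
      sprintf("%.4g mm\n", object@stage1Rms))
  print(object@table, digits = 4)
})

#' @describeIn ToothMotionReport-class the per-tooth parameter table.
#' @param report a \code{ToothMotionReport}.
#' @export
motionTable <- function(report) report@table

#' @describeIn ToothMotionReport-class world-frame motion transforms.
#' @export
motionTransforms <- function(report) report@transforms

#' Two-stage rugae-anchored estimation of per-tooth rigid motion
#'
#' Stage 0: if landmark sets are supplied, the post-treatment scan is
#' roughly initialized by aligning its anatomical frame onto the
#' pre-treatment frame. Stage 1: ICP on the rugae vertices only; the
#' resulting transform aligns the entire post scan to the stable rugae
#' patch. Stage 2: for every tooth class present in both meshes, ICP of the
#' (stage-1 aligned) post tooth onto the pre tooth. The world-frame motion
#' of each tooth (pre to post, net of global scan pose) is
#' \code{H1 . H2^-1}, where \code{H1} is the stage-1 global alignment and
#' \code{H2} the per-tooth alignment; it is decomposed into three rotations
#' and three translations with [decomposeTransform()]. When landmarks are
#' given, the reported parameters are expressed in the pre-scan anatomical
#' frame, so they are invariant to how either scan happened to sit in
#' world coordinates.
#'
#' @param preMesh,postMesh segmented [LabeledMesh-class] objects sharing a
#'   scheme; both must contain rugae vertices.
#' @param preLandmarks,postLandmarks optional landmark lists (see
#'   [buildFrame()]) for the stage-0 initialization.
#' @param maxIter,tol,trimFraction ICP parameters, see [icp()].
#' @param restartRms per-tooth residual (mm) above which ICP is restarted
#'   from a small set of rotated initializations about the tooth centroid
#'   (point-to-point ICP is a local optimizer; crowns are compact enough
#'   that a handful of restarts reliably escape wrong basins). The best
#'   residual wins. Set to 0 to disable.
#' @return a [ToothMotionReport-class].
#' @export
estimateToothMotions <- function(preMesh, postMesh,
                                 preLandmarks = NULL, postLandmarks = NULL,
                                 maxIter = 100L, tol = 1e-10,
                                 trimFraction = 0, restartRms = 0.05) {
  scheme <- preMesh@scheme
  rug <- rugaeLabel(scheme)
  preRug <- preMesh@vertices[preMesh@label == rug, , drop = FALSE]
  postRug <- postMesh@vertices[postMesh@label == rug, , drop = FALSE]
  if (nrow(preRug) == 0L) stop("pre-treatment mesh has no rugae vertices")
  if (nrow(postRug) == 0L) stop("post-treatment mesh has no rugae vertices")

  init <- NULL
  preFrame <- NULL
  if (!is.null(preLandmarks) && !is.null(postLandmarks)) {
    preFrame <- buildFrame(preLandmarks)
    init <- frameAlignment(buildFrame(postLandmarks), preFrame)
  }

  stage1 <- icp(postRug, preRug, maxIter = maxIter, tol = tol,
                trimFraction = trimFraction, init = init)
  H1 <- stage1$transform@H

  teeth <- toothLabels(scheme)
  preT <- intersect(teeth, unique(preMesh@label))
  postT <- intersect(teeth, unique(postMesh@label))
  both <- intersect(preT, postT)
  unmatched <- sort(union(setdiff(preT, postT), setdiff(postT, preT)))

  W <- if (is.null(preFrame)) diag(4) else worldToFrame(preFrame)@H
  Winv <- solve(W)

  rows <- list()
  transforms <- list()
  for (id in both) {
    p <- preMesh@vertices[preMesh@label == id, , drop = FALSE]
    q <- postMesh@vertices[postMesh@label == id, , drop = FALSE]
    # stage-2 init: stage-1 alignment plus a centroid shift, so the ICP
    # starts translation-free and only the residual rotation is at stake
    Hinit <- H1
    Hinit[1:3, 4] <- Hinit[1:3, 4] + colMeans(p) -
      colMeans(transformPoints(H1, q))
    fit <- icp(q, p, maxIter = maxIter, tol = tol,
               trimFraction = trimFraction,
               init = rigidTransform(Hinit))
    if (restartRms > 0 && fit$rms > restartRms) {
      for (Halt in .restartInits(q, p, Hinit)) {
        alt <- icp(q, p, maxIter = maxIter, tol = tol,
                   trimFraction = trimFraction, init = rigidTransform(Halt))
        if (alt$rms < fit$rms) fit <- alt
        if (fit$rms <= restartRms) break
      }
    }
    Hmotion <- H1 %*% solve(fit$transform@H)   # pre -> post, world frame
    params <- decomposeTransform(rigidTransform(W %*% Hmotion %*% Winv))
    nm <- labelName(scheme, id)
    transforms[[nm]] <- rigidTransform(Hmotion)
    rows[[nm]] <- data.frame(
      id = id, name = nm,
      alpha = params@alpha, beta = params@beta, gamma = params@gamma,
      tx = params@tx, ty = params@ty, tz = params@tz,
      rms = fit$rms, gimbal = params@gimbal,
      stringsAsFactors = FALSE
    )
  }
  tab <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else data.frame()
  new("ToothMotionReport", table = tab, transforms = transforms,
      stage1Rms = stage1$rms, unmatched = as.integer(unmatched))
}

#' Write a motion report as CSV
#'
#' One row per tooth: label, rotations (deg), translations (mm), ICP
#' residual RMS. Optionally a JSON sidecar with the full 4 x 4 world-frame
#' matrices, row-major.
#' @param report a [ToothMotionReport-class].
#' @param path output CSV path.
#' @param jsonPath optional path for the matrix sidecar.
#' @export
writeMotionReport <- function(report, path, jsonPath = NULL) {
  utils::write.csv(report@table, path, row.names = FALSE)
  if (!is.null(jsonPath)) {
    mats <- lapply(report@transforms, function(tr) as.vector(t(tr@H)))
    jsonlite::write_json(
      list(stage1_rms = report@stage1Rms, transforms_row_major = mats),
      jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
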