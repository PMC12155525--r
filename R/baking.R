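# Back-projection ("baking") of per-pixel label predictions onto mesh
# vertices, multi-view vote accumulation, and 3D segmentation.

#' Observe per-vertex labels from one predicted view
#'
#' Back-projects one prediction through the saved camera pose. Two
#' observation rules are available:
#' \describe{
#'   \item{\code{"ownership"} (default)}{the mesh is re-rasterized at the
#'     pose; every covered pixel is owned by the nearest vertex (largest
#'     barycentric weight) of its front face -- the same vertex whose
#'     label the ground-truth render would show there -- and each vertex
#'     observes the majority predicted label over the pixels it owns.
#'     This makes the ground-truth closed loop exact: label boundaries
#'     never leak across vertices.}
#'   \item{\code{"depth"}}{the classic shadow-mapping test: a vertex is
#'     visible iff its projected depth matches the supplied depth buffer
#'     at its pixel within \code{tolerance}, and observes the predicted
#'     label at that pixel.}
#' }
#' In both rules a vertex projecting outside the image, onto background,
#' or occluded observes nothing (\code{NA}).
#'
#' @param mesh the [LabeledMesh-class] being segmented.
#' @param pose the exact [CameraPose-class] the prediction's input was
#'   rendered with.
#' @param predictedLabels the predicted label image: an H x W x 3 palette
#'   raster in [0,1], or an integer H x W class-id matrix.
#' @param depth the H x W depth buffer of that render (required for
#'   \code{method = "depth"}; checked for size if supplied).
#' @param method observation rule, see above.
#' @param tolerance depth-match tolerance (mm) for \code{method="depth"};
#'   default 1e-3 of the scene diameter plus one pixel of surface slope.
#' @return integer vector of length N: observed class id per vertex, NA
#'   where the vertex cast no observation in this view.
#' @export
bakeView <- function(mesh, pose, predictedLabels, depth = NULL,
                     method = c("ownership", "depth"), tolerance = NULL) {
  method <- match.arg(method)
  if (length(dim(predictedLabels)) == 3L) {
    predictedLabels <- decodeLabelImage(predictedLabels, mesh@scheme)
  }
  if (!is.null(depth) && !all(dim(predictedLabels) == dim(depth))) {
    stop("prediction and depth buffer sizes differ")
  }
  if (nrow(predictedLabels) != pose@height ||
      ncol(predictedLabels) != pose@width) {
    stop("prediction does not match the pose's image size")
  }
  n <- nrow(mesh@vertices)
  obs <- rep(NA_integer_, n)

  if (method == "ownership") {
    ras <- .renderCore(mesh, pose)
    hit <- which(ras$face > 0)
    if (length(hit) == 0L) return(obs)
    f <- ras$face[hit]
    w <- cbind(ras$b1[hit], ras$b2[hit], 1 - ras$b1[hit] - ras$b2[hit])
    corner <- max.col(w, ties.method = "first")
    owner <- mesh@faces[cbind(f, corner)]
    lab <- predictedLabels[hit]
    # per-vertex majority over owned pixels (ties -> lowest label id)
    o <- order(owner, lab)
    owner <- owner[o]; lab <- lab[o]
    key <- paste(owner, lab)
    cnt <- rle(key)$lengths
    firsts <- cumsum(c(1L, cnt[-length(cnt)]))
    vOwner <- owner[firsts]
    vLab <- lab[firsts]
    best <- tapply(seq_along(cnt), vOwner, function(ii) {
      ii[which.max(cnt[ii])]          # lab sorted ascending: first max wins
    })
    obs[vOwner[best]] <- vLab[best]
    return(obs)
  }

  if (is.null(depth)) stop("method 'depth' needs the view's depth buffer")
  bs <- boundingSphere(mesh)
  if (is.null(tolerance)) {
    tolerance <- 2e-3 * bs$radius + 4 * bs$radius / pose@width
  }
  pr <- projectPoints(pose, mesh@vertices)
  col <- floor(pr$px) + 1L
  row <- floor(pr$py) + 1L
  inimg <- col >= 1L & col <= pose@width & row >= 1L & row <= pose@height &
           pr$z > 0
  idx <- which(inimg)
  if (length(idx)) {
    lin <- cbind(row[idx], col[idx])
    d <- depth[lin]
    vis <- is.finite(d) & abs(d - pr$z[idx]) < tolerance
    obs[idx[vis]] <- predictedLabels[lin[vis, , drop = FALSE]]
  }
  obs
}

#' Accumulate per-vertex label votes over views
#'
#' @param observations list of per-vertex observation vectors from
#'   [bakeView()], all over the same mesh.
#' @param scheme a [LabelScheme-class].
#' @return a list with \code{votes} (N x K integer matrix, one column per
#'   scheme label) and \code{visibility} (integer vector, number of views
#'   in which each vertex cast a vote; equals \code{rowSums(votes)}).
#' @export
accumulateVotes <- function(observations, scheme = defaultLabelScheme()) {
  ids <- scheme@entries$id
  if (length(observations) == 0L) {
    stop("no observations; pass at least an empty-view list with known N")
  }
  n <- length(observations[[1]])
  votes <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
  for (obs in observations) {
    if (length(obs) != n) stop("observations refer to different meshes")
    seen <- which(!is.na(obs))
    if (length(seen)) {
      k <- match(obs[seen], ids)
      if (anyNA(k)) stop("observed label not in scheme")
      # each vertex observes at most once per view, so increment directly
      votes[cbind(seen, k)] <- votes[cbind(seen, k)] + 1L
    }
  }
  list(votes = votes, visibility = as.integer(rowSums(votes)))
}

#' Final per-vertex labels from a vote tally
#'
#' Majority vote per vertex; ties broken deterministically by the lowest
#' label id; vertices never visible in any view get void.
#'
#' @param tally result of [accumulateVotes()].
#' @param scheme a [LabelScheme-class].
#' @return integer vector of class ids, one per vertex.
#' @export
finalizeLabels <- function(tally, scheme = defaultLabelScheme()) {
  votes <- tally$votes
  ids <- as.integer(colnames(votes))
  ord <- order(ids)                       # columns in id order => lowest-id ties
  votes <- votes[, ord, drop = FALSE]
  ids <- ids[ord]
  lab <- ids[max.col(votes, ties.method = "first")]
  lab[tally$visibility == 0L] <- voidLabel(scheme)
  as.integer(lab)
}

#' Split a labeled mesh into per-label submeshes
#'
#' One submesh per non-void label present. Vertices are partitioned by
#' label; a face is assigned to the majority label of its three vertices
#' (ties to the lowest label id) and kept only in that label's submesh.
#'
#' @param mesh a [LabeledMesh-class].
#' @return named list of [LabeledMesh-class], one per non-void label.
#' @export
segmentComponents <- function(mesh) {
  scheme <- mesh@scheme
  void <- voidLabel(scheme)
  present <- sort(setdiff(unique(mesh@label), void))
  f <- mesh@faces
  fl1 <- mesh@label[f[, 1]]; fl2 <- mesh@label[f[, 2]]; fl3 <- mesh@label[f[, 3]]
  # majority of the three corner labels; all-distinct ties -> lowest id
  faceLab <- ifelse(fl1 == fl2 | fl1 == fl3, fl1,
                    ifelse(fl2 == fl3, fl2, pmin(fl1, fl2, fl3)))
  out <- list()
  for (id in present) {
    vs <- which(mesh@label == id)
    remap <- integer(nrow(mesh@vertices))
    remap[vs] <- seq_along(vs)
    ff <- f[faceLab == id, , drop = FALSE]
    keep <- rowSums(matrix(ff %in% vs, ncol = 3)) == 3L
    ff <- matrix(remap[ff[keep, ]], ncol = 3)
    out[[labelName(scheme, id)]] <- LabeledMesh(
      mesh@vertices[vs, , drop = FALSE], ff,
      color = mesh@color[vs, , drop = FALSE],
      label = mesh@label[vs], scheme = scheme)
  }
  out
}

#' Vertex-level segmentation metrics
#'
#' Per-class intersection-over-union evaluated on vertex sets, plus the
#' per-scan mean over classes present in either labeling (classes absent
#' from both are undefined and excluded, matching the convention of
#' reporting a dash for missing classes).
#'
#' @param predLabels,trueLabels integer vectors of class ids, same length.
#' @param scheme a [LabelScheme-class].
#' @param subset optional logical/integer vector restricting the evaluation
#'   to a vertex subset (e.g. vertices visible in at least one view).
#' @return list with \code{perClass} (named numeric, NA = undefined) and
#'   \code{meanIoU}.
#' @export
metrics3D <- function(predLabels, trueLabels, scheme = defaultLabelScheme(),
                      subset = NULL) {
  if (length(predLabels) != length(trueLabels)) {
    stop("label vectors have different lengths")
  }
  if (!is.null(subset)) {
    predLabels <- predLabels[subset]
    trueLabels <- trueLabels[subset]
  }
  ids <- scheme@entries$id
  iou <- stats::setNames(rep(NA_real_, length(ids)), scheme@entries$name)
  for (k in seq_along(ids)) {
    p <- predLabels == ids[k]
    t <- trueLabels == ids[k]
    u <- sum(p | t)
    if (u > 0) iou[k] <- sum(p & t) / u
  }
  list(perClass = iou, meanIoU = mean(iou, na.rm = TRUE))
}

#' Write per-class vertex IoU as CSV
#' @param m3 result of [metrics3D()].
#' @param path output path.
#' @export
writeMetrics3D <- function(m3, path) {
  utils::write.csv(
    data.frame(class = names(m3$perClass), iou = as.numeric(m3$perClass)),
    path, row.names = FALSE)
  invisible(path)
}
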